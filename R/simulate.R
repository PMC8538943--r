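# Seeded simulators: a reference species complex with controlled K2P
# divergence structure, paired Sanger-style reads, and instar-structured
# larval field seasons.  Everything the pipeline consumes can be generated
# here with truth tables retained, so every stage is testable offline.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

#' Random nucleotide sequence
#' @param length sequence length.
#' @return an ACGT string.  Uses the current RNG state.
#' @export
random_seq <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# K2P per-site event probabilities after an expected distance d with
# transition/transversion rate ratio kappa:  with beta*t = d/(kappa+2) and
# alpha = kappa*beta,  P = 1/4 + exp(-4bt)/4 - exp(-2(a+b)t)/2 and
# Q = 1/2 - exp(-4bt)/2, so that the K2P estimator recovers d exactly in
# expectation.
k2p_site_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  c(P = P, Q = Q)
}

#' Mutate a sequence under the Kimura-2-parameter process
#'
#' Runs the K2P substitution process so that the expected K2P distance
#' between input and output equals `target_distance`, with
#' transition:transversion rate ratio `kappa`.  No indels; length is
#' preserved; non-ACGT positions are left untouched.  Uses the current RNG
#' state (seed at the caller).
#'
#' @param seq ACGT (IUPAC) string.
#' @param target_distance expected K2P distance (>= 0).
#' @param kappa transition/transversion rate ratio (> 0, default 4).
#' @return the mutated sequence.
#' @export
mutate_k2p <- function(seq, target_distance, kappa = 4) {
  if (target_distance < 0) stop("target_distance must be >= 0", call. = FALSE)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (target_distance == 0) return(seq)
  pq <- k2p_site_probs(target_distance, kappa)
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  u <- runif(n)
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transv1 <- c(A = "C", G = "C", C = "A", T = "A")
  transv2 <- c(A = "T", G = "T", C = "G", T = "G")
  std <- ch %in% c("A", "C", "G", "T")
  ts <- std & u < pq["P"]
  tv <- std & u >= pq["P"] & u < pq["P"] + pq["Q"]
  pick2 <- runif(n) < 0.5
  ch[ts] <- transition[ch[ts]]
  ch[tv & pick2] <- transv1[ch[tv & pick2]]
  ch[tv & !pick2] <- transv2[ch[tv & !pick2]]
  paste(ch, collapse = "")
}

#' Configuration of a simulated reference species complex
#'
#' Defaults emulate a 640 bp COI complex of six congeneric species with a
#' deep interspecific split (K2P 0.15), low intraspecific divergence
#' (K2P 0.02) except one variable species at K2P 0.06 split into two
#' subclades — the structure observed in billbug COI barcodes.
#'
#' @param n_species number of species (default 6).
#' @param seq_length barcode length in bp (default 640).
#' @param interspecific_k2p expected K2P distance between species ancestors
#'   (default 0.15); must exceed every intraspecific level.
#' @param intraspecific_k2p per-species expected intraspecific K2P
#'   distances; recycled.  Default: 0.06 for the first species (the
#'   variable, subclade-structured one) and 0.02 for the rest.
#' @param subclade_species index of the species split into two subclades
#'   (default 1; `NA` for none).
#' @param kappa transition/transversion rate ratio (default 4, a typical
#'   insect mitochondrial bias).
#' @param n_refs_per_species labelled adult references per species
#'   (default 5).
#' @param n_queries_per_species unlabelled queries per species (default 0).
#' @param seed integer seed.
#' @return object of class `complex_config`.
#' @export
complex_config <- function(n_species = 6L, seq_length = 640L,
                           interspecific_k2p = 0.15,
                           intraspecific_k2p = NULL,
                           subclade_species = 1L, kappa = 4,
                           n_refs_per_species = 5L,
                           n_queries_per_species = 0L, seed = 1L) {
  if (is.null(intraspecific_k2p))
    intraspecific_k2p <- c(0.06, rep(0.02, max(0L, n_species - 1L)))
  intraspecific_k2p <- rep_len(intraspecific_k2p, n_species)
  if (any(intraspecific_k2p < 0) || interspecific_k2p < 0 || kappa <= 0)
    stop("rates must be >= 0 and kappa > 0", call. = FALSE)
  if (interspecific_k2p <= max(intraspecific_k2p))
    stop("interspecific_k2p must exceed every intraspecific level",
         call. = FALSE)
  structure(list(n_species = as.integer(n_species),
                 seq_length = as.integer(seq_length),
                 interspecific_k2p = interspecific_k2p,
                 intraspecific_k2p = intraspecific_k2p,
                 subclade_species = subclade_species, kappa = kappa,
                 n_refs_per_species = as.integer(n_refs_per_species),
                 n_queries_per_species = as.integer(n_queries_per_species),
                 seed = as.integer(seed)),
            class = "complex_config")
}

#' Simulate a labelled reference species complex
#'
#' A random root sequence is mutated to `interspecific_k2p / 2` along a
#' star species tree to create species ancestors (pairwise ancestor
#' distance = `interspecific_k2p`); members are mutated from their
#' ancestor at half the species' intraspecific level.  The subclade
#' species first splits into two sub-ancestors so that cross-subclade
#' members sit at the full intraspecific distance while members within a
#' subclade stay at the lowest level.
#'
#' @param config a [complex_config()].
#' @return list with `references` (labelled [barcode_set()]), `queries`
#'   ([barcode_set()], unlabelled; empty when `n_queries_per_species` is
#'   0), `truth` (data frame id, species, subclade, role), `tree` (the
#'   generating species star tree as `phylo`) and `config`.
#' @export
simulate_reference_complex <- function(config = complex_config()) {
  stopifnot(inherits(config, "complex_config"))
  with_seed(config$seed, {
    ns <- config$n_species
    species <- sprintf("species_%s", LETTERS[seq_len(ns)])
    root <- random_seq(config$seq_length)
    half_inter <- config$interspecific_k2p / 2
    ancestors <- lapply(seq_len(ns), function(i)
      mutate_k2p(root, half_inter, config$kappa))
    min_intra <- min(config$intraspecific_k2p)
    make_member <- function(i) {
      d_intra <- config$intraspecific_k2p[i]
      if (!is.na(config$subclade_species) && i == config$subclade_species &&
          d_intra > min_intra) {
        # two subclades: deep split between sub-ancestors, shallow tips
        sub_split <- (d_intra - min_intra) / 2
        sub_anc <- lapply(1:2, function(k)
          mutate_k2p(ancestors[[i]], sub_split, config$kappa))
        function() {
          k <- sample.int(2L, 1L)
          list(seq = mutate_k2p(sub_anc[[k]], min_intra / 2, config$kappa),
               subclade = paste0("sub", k))
        }
      } else {
        function() list(seq = mutate_k2p(ancestors[[i]], d_intra / 2,
                                         config$kappa), subclade = "")
      }
    }
    makers <- lapply(seq_len(ns), make_member)
    truth <- list(); ref_seq <- character(0); qry_seq <- character(0)
    for (i in seq_len(ns)) {
      for (r in seq_len(config$n_refs_per_species)) {
        id <- sprintf("ad_%s_%02d", species[i], r)
        mem <- makers[[i]]()
        ref_seq[id] <- mem$seq
        truth[[length(truth) + 1L]] <-
          data.frame(id = id, species = species[i], subclade = mem$subclade,
                     role = "reference", stringsAsFactors = FALSE)
      }
      for (q in seq_len(config$n_queries_per_species)) {
        id <- sprintf("lv_%s_%02d", species[i], q)
        mem <- makers[[i]]()
        qry_seq[id] <- mem$seq
        truth[[length(truth) + 1L]] <-
          data.frame(id = id, species = species[i], subclade = mem$subclade,
                     role = "query", stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    refs <- barcode_set(ref_seq,
                        data.frame(id = names(ref_seq),
                                   species = truth$species[
                                     match(names(ref_seq), truth$id)],
                                   stage = "adult", locus = "COI",
                                   stringsAsFactors = FALSE))
    queries <- if (length(qry_seq))
      barcode_set(qry_seq, data.frame(id = names(qry_seq), stage = "larva",
                                      locus = "COI", stringsAsFactors = FALSE))
    else NULL
    tree <- ape::read.tree(text = paste0(
      "(", paste(sprintf("%s:%g", species, half_inter), collapse = ","), ");"))
    list(references = refs, queries = queries, truth = truth, tree = tree,
         config = config)
  })
}

#' Simulate a forward/reverse Sanger-style read pair
#'
#' The amplicon is `forward_primer + template + revcomp(reverse_primer)`.
#' The forward read is its first `read_length` bases; the reverse read is
#' the reverse complement of its last `read_length` bases (so it starts
#' with the reverse primer).  Base-call errors are injected at
#' `error_rate` with lowered qualities, either uniformly or concentrated
#' in the low-quality 3' tail, and each read additionally decays to
#' `tail_quality` over its last `tail_length` bases, emulating Sanger end
#' noise.
#'
#' @param template ACGT template string (e.g. a 640 bp barcode).
#' @param primers a [primer_pair()].
#' @param read_length read length (default 450); must not exceed the
#'   amplicon length.
#' @param error_rate per-base substitution error probability (default 0).
#' @param quality_profile list with `base_quality` (default 50),
#'   `err_quality` (quality written at error positions, default 10),
#'   `tail_length` (default 30) and `tail_quality` (default 5).
#' @param error_placement `"uniform"` or `"tail"` (errors restricted to the
#'   low-quality tail).
#' @return list with `forward` and `reverse` [trace_read()]s.
#' @export
simulate_reads <- function(template, primers, read_length = 450L,
                           error_rate = 0,
                           quality_profile = list(base_quality = 50L,
                                                  err_quality = 10L,
                                                  tail_length = 30L,
                                                  tail_quality = 5L),
                           error_placement = c("uniform", "tail")) {
  error_placement <- match.arg(error_placement)
  stopifnot(inherits(primers, "primer_pair"))
  qp <- quality_profile
  need <- c("base_quality", "err_quality", "tail_length", "tail_quality")
  if (!all(need %in% names(qp)))
    stop("quality_profile needs fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  amplicon <- paste0(primers$forward_primer, template,
                     reverse_complement(primers$reverse_primer))
  la <- nchar(amplicon)
  if (read_length > la)
    stop("read_length exceeds amplicon length (", la, ")", call. = FALSE)
  fwd_bases <- substr(amplicon, 1L, read_length)
  rev_bases <- reverse_complement(substr(amplicon, la - read_length + 1L, la))
  degrade <- function(bases) {
    ch <- strsplit(bases, "")[[1L]]
    n <- length(ch)
    q <- rep(as.integer(qp$base_quality), n)
    tail_idx <- if (qp$tail_length > 0L)
      seq.int(max(1L, n - qp$tail_length + 1L), n) else integer(0)
    q[tail_idx] <- as.integer(qp$tail_quality)
    if (error_rate > 0) {
      pool <- if (error_placement == "tail") tail_idx else seq_len(n)
      err <- pool[runif(length(pool)) < error_rate]
      for (k in err) {
        ch[k] <- sample(setdiff(c("A", "C", "G", "T"), ch[k]), 1L)
        q[k] <- min(q[k], as.integer(qp$err_quality))
      }
    }
    list(bases = paste(ch, collapse = ""), q = q)
  }
  f <- degrade(fwd_bases)
  r <- degrade(rev_bases)
  list(forward = trace_read(f$bases, f$q, "forward"),
       reverse = trace_read(r$bases, r$q, "reverse"))
}

#' Configuration of a simulated larval field season
#'
#' Defaults emulate an early-season turfgrass collection campaign
#' (21 May - 26 July, weekly-ish collections) with five instars whose
#' head-capsule means (0.5/0.8/1.2/1.6/2.0 mm, sd 0.08) are synthetic
#' values consistent with the conventional small/medium/large bin
#' thresholds, and a seasonal progression from early to late instars.
#'
#' @param start,end season window, ISO dates.
#' @param n_collections number of evenly spaced collection dates.
#' @param sites data frame with columns `site_code`, `grass_type`
#'   (`cool_season`/`warm_season`) and a `mixture` list-column of named
#'   species proportions (must sum to 1 per site).
#' @param n_per_collection larvae per site per collection date.
#' @param instar_means,instar_sd head-capsule width distribution per
#'   instar (mm), strictly increasing means.
#' @param progression_sd spread (in instars) around the seasonal mean
#'   instar, which advances linearly from 1 to 5 across the window.
#' @param seed integer seed.
#' @return object of class `season_config`.
#' @export
season_config <- function(start = "2018-05-21", end = "2018-07-26",
                          n_collections = 8L,
                          sites = NULL, n_per_collection = 6L,
                          instar_means = c(0.5, 0.8, 1.2, 1.6, 2.0),
                          instar_sd = 0.08, progression_sd = 0.7,
                          seed = 1L) {
  if (is.null(sites)) {
    sites <- data.frame(site_code = c("S1", "S2"),
                        grass_type = c("cool_season", "warm_season"),
                        stringsAsFactors = FALSE)
    sites$mixture <- list(c(species_A = 0.68, species_B = 0.12,
                            species_C = 0.20),
                          c(species_A = 0.92, species_B = 0.06,
                            species_C = 0.02))
  }
  if (any(diff(instar_means) <= 0))
    stop("instar means must be strictly increasing", call. = FALSE)
  for (i in seq_len(nrow(sites))) {
    mx <- sites$mixture[[i]]
    if (abs(sum(mx) - 1) > 1e-8)
      stop("mixture proportions must sum to 1 per site (site ",
           sites$site_code[i], ")", call. = FALSE)
    if (!length(mx)) stop("empty mixture for site ", sites$site_code[i],
                          call. = FALSE)
  }
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || end <= start)
    stop("invalid season window", call. = FALSE)
  structure(list(start = start, end = end,
                 n_collections = as.integer(n_collections), sites = sites,
                 n_per_collection = as.integer(n_per_collection),
                 instar_means = instar_means, instar_sd = instar_sd,
                 progression_sd = progression_sd, seed = as.integer(seed)),
            class = "season_config")
}

#' Simulate a larval field season over a reference complex
#'
#' For each collection date and site, species are drawn from the site's
#' mixture, the instar from a seasonal progression schedule (mean instar
#' advances linearly from 1 to 5 across the window), and the head-capsule
#' width from the instar's normal distribution truncated above 0.  Each
#' larva carries a query COI sequence simulated from its species (drawn
#' with the same divergence machinery as the reference complex).
#'
#' @param complex result of [simulate_reference_complex()].
#' @param season a [season_config()].
#' @return list with `records` (data frame of larval records including the
#'   true species in `true_species`; `species` is left `"unassigned"` for
#'   the pipeline to fill), `queries` (a [barcode_set()] of larval
#'   sequences) and `season`.
#' @export
simulate_larval_season <- function(complex, season = season_config()) {
  stopifnot(inherits(season, "season_config"))
  cfg <- complex$config
  with_seed(season$seed, {
    # regenerate the per-species sequence generators from the complex seed
    base <- simulate_reference_complex(cfg)
    # member generator: mutate a random existing reference of the species
    ref_by_sp <- split(names(base$references$seq),
                       base$references$meta$species)
    dates <- seq(season$start, season$end,
                 length.out = season$n_collections)
    n_inst <- length(season$instar_means)
    rows <- list(); seqs <- character(0)
    counter <- 0L
    for (ci in seq_along(dates)) {
      f <- if (season$n_collections > 1L)
        (ci - 1) / (season$n_collections - 1) else 0.5
      mean_instar <- 1 + f * (n_inst - 1)
      for (si in seq_len(nrow(season$sites))) {
        site <- season$sites$site_code[si]
        grass <- season$sites$grass_type[si]
        mix <- season$sites$mixture[[si]]
        for (k in seq_len(season$n_per_collection)) {
          counter <- counter + 1L
          sp <- sample(names(mix), 1L, prob = mix)
          instar <- min(n_inst, max(1L, round(rnorm(1L, mean_instar,
                                                    season$progression_sd))))
          hw <- -1
          while (hw <= 0)
            hw <- rnorm(1L, season$instar_means[instar], season$instar_sd)
          id <- sprintf("lv_%03d", counter)
          anc <- base$references$seq[[sample(ref_by_sp[[sp]], 1L)]]
          seqs[id] <- mutate_k2p(anc, min(cfg$intraspecific_k2p) / 2,
                                 cfg$kappa)
          rows[[counter]] <- data.frame(
            id = id, species = "unassigned", true_species = sp,
            instar = instar, head_capsule_mm = round(hw, 3),
            collection_date = as.character(dates[ci]), site_code = site,
            grass_type = grass, stringsAsFactors = FALSE)
        }
      }
    }
    records <- do.call(rbind, rows)
    queries <- barcode_set(seqs,
                           data.frame(id = names(seqs), stage = "larva",
                                      locus = "COI",
                                      stringsAsFactors = FALSE))
    list(records = records, queries = queries, season = season)
  })
}
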