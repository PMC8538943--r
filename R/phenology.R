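# Seasonal phenology tables and species-composition summaries from
# identified larvae and head-capsule morphometrics.

#' Head-capsule size bins
#'
#' Larvae are binned as small (< `small_upper` mm), medium
#' (`small_upper`-`large_lower` mm, closed interval) or large
#' (> `large_lower` mm), the conventional 3-class reduction of the five
#' billbug instars.
#'
#' @param small_upper upper bound of "small" in mm (default 1.0).
#' @param large_lower lower bound of "large" in mm (default 1.7).
#' @return object of class `size_bins`.
#' @export
size_bins <- function(small_upper = 1.0, large_lower = 1.7) {
  if (!(small_upper > 0 && small_upper < large_lower))
    stop("need 0 < small_upper < large_lower", call. = FALSE)
  structure(list(small_upper = small_upper, large_lower = large_lower),
            class = "size_bins")
}

#' Bin a head-capsule width
#'
#' Boundary widths fall in the medium class: `width < small_upper` is
#' small, `small_upper <= width <= large_lower` is medium, anything larger
#' is large.
#'
#' @param width head-capsule width(s) in mm, positive.
#' @param bins a [size_bins()].
#' @return factor with levels `small`, `medium`, `large`.
#' @examples
#' bin_size(c(0.8, 1.0, 1.7, 1.71))
#' @export
bin_size <- function(width, bins = size_bins()) {
  stopifnot(inherits(bins, "size_bins"))
  width <- as.numeric(width)
  if (any(is.na(width)) || any(width <= 0))
    stop("head-capsule widths must be positive", call. = FALSE)
  out <- ifelse(width < bins$small_upper, "small",
                ifelse(width <= bins$large_lower, "medium", "large"))
  factor(out, levels = c("small", "medium", "large"))
}

#' Ordinal day of the year
#'
#' Leap-aware: 1 for January 1st, up to 366.
#'
#' @param date a `Date` or ISO-8601 string (vectorised).
#' @return integer day(s) of year.
#' @examples
#' day_of_year("2020-06-03")  # 155 (leap year)
#' @export
day_of_year <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (any(is.na(d)))
    stop("invalid date(s): ",
         paste(date[is.na(d)], collapse = ", "), call. = FALSE)
  as.POSIXlt(d)$yday + 1L
}

#' Build a phenology table from identified larval records
#'
#' @param records data frame with columns `id`, `species` (possibly
#'   `"unassigned"`), `head_capsule_mm`, `collection_date`, `site_code`,
#'   `grass_type`.
#' @param bins a [size_bins()].
#' @return object of class `phenology_table`: list with `table` (long-form
#'   rows: species, day_of_year, head_capsule_mm, size_class, site_code,
#'   grass_type, year, week), `counts` (per species x size_class x week),
#'   and `n_unassigned` (records excluded from species panels).
#' @export
build_phenology <- function(records, bins = size_bins()) {
  records <- as.data.frame(records)
  need <- c("id", "species", "head_capsule_mm", "collection_date",
            "site_code", "grass_type")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(records$head_capsule_mm)) ||
      any(records$head_capsule_mm <= 0) ||
      any(records$head_capsule_mm >= 5))
    stop("head_capsule_mm must lie in (0, 5) mm", call. = FALSE)
  unass <- is.na(records$species) | records$species %in% c("", "unassigned")
  if (all(unass)) stop("all records are unassigned", call. = FALSE)
  kept <- records[!unass, , drop = FALSE]
  kept <- kept[order(kept$id), , drop = FALSE]
  d <- as.Date(kept$collection_date)
  tab <- data.frame(id = kept$id, species = kept$species,
                    day_of_year = day_of_year(d),
                    head_capsule_mm = kept$head_capsule_mm,
                    size_class = bin_size(kept$head_capsule_mm, bins),
                    site_code = kept$site_code,
                    grass_type = kept$grass_type,
                    year = as.integer(format(d, "%Y")),
                    week = as.integer(format(d, "%V")),
                    stringsAsFactors = FALSE)
  counts <- aggregate(list(n = tab$id),
                      by = list(species = tab$species,
                                size_class = tab$size_class,
                                week = tab$week), FUN = length)
  counts <- counts[order(counts$species, counts$week, counts$size_class), ]
  rownames(counts) <- NULL
  structure(list(table = tab, counts = counts, n_unassigned = sum(unass),
                 bins = bins),
            class = "phenology_table")
}

#' @export
print.phenology_table <- function(x, ...) {
  cat(sprintf("phenology_table: %d identified larvae (%d unassigned excluded)\n",
              nrow(x$table), x$n_unassigned))
  with(x$table, {
    cat(sprintf("  species: %s\n",
                paste(sprintf("%s=%d", names(table(species)), table(species)),
                      collapse = ", ")))
    cat(sprintf("  day of year %d-%d; size classes: %s\n",
                min(day_of_year), max(day_of_year),
                paste(sprintf("%s=%d", names(table(size_class)),
                              table(size_class)), collapse = ", ")))
  })
  invisible(x)
}

# round half away from zero (base round() is half-to-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Species composition per group
#'
#' Percentage of each species among the identified records of each group,
#' rounded to the nearest integer (half away from zero); raw counts are
#' reported alongside so any rounding can be audited.  Unassigned records
#' are excluded from percentages.
#'
#' @param records data frame with a `species` column; unassigned records
#'   carry `""`, `NA` or `"unassigned"`.
#' @param group_by name of the grouping column (default `"grass_type"`).
#' @return data frame with columns `group`, `species`, `n`, `group_total`,
#'   `pct`.
#' @examples
#' rec <- data.frame(species = rep(c("a", "b", "c"), c(28, 5, 8)),
#'                   grass_type = "cool_season")
#' composition_summary(rec)  # 68 / 12 / 20
#' @export
composition_summary <- function(records, group_by = "grass_type") {
  records <- as.data.frame(records)
  if (!group_by %in% names(records))
    stop("records lack grouping column '", group_by, "'", call. = FALSE)
  groups <- unique(as.character(records[[group_by]]))
  out <- list()
  for (g in groups) {
    sub <- records[records[[group_by]] == g, , drop = FALSE]
    idd <- !(is.na(sub$species) | sub$species %in% c("", "unassigned"))
    if (!any(idd)) {
      warning("group '", g, "' has no identified records; omitted",
              call. = FALSE)
      next
    }
    counts <- table(sub$species[idd])
    out[[g]] <- data.frame(group = g, species = names(counts),
                           n = as.integer(counts),
                           group_total = sum(idd),
                           pct = as.numeric(
                             round_half_away(100 * as.integer(counts) /
                                               sum(idd))),
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no identified records in any group", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group, -res$n, res$species), , drop = FALSE]
}

#' Write phenology outputs to CSV
#' @param x a `phenology_table`.
#' @param path long-form table CSV; aggregated counts go to
#'   `paste0(path, ".counts.csv")` unless `counts_path` is given.
#' @param counts_path optional counts CSV path.
#' @return `path`, invisibly.
#' @export
write_phenology_csv <- function(x, path, counts_path = NULL) {
  stopifnot(inherits(x, "phenology_table"))
  write.csv(x$table, path, row.names = FALSE)
  if (is.null(counts_path)) counts_path <- paste0(path, ".counts.csv")
  write.csv(x$counts, counts_path, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of head-capsule width against day of year
#'
#' Cosmetic convenience layer over the phenology table: one panel of
#' points per species, akin to the classic larval phenology chart.
#'
#' @param x a `phenology_table`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phenology_table <- function(x, ...) {
  tab <- x$table
  sp <- factor(tab$species)
  graphics::plot(tab$day_of_year, tab$head_capsule_mm, col = as.integer(sp),
                 pch = 19, xlab = "day of year",
                 ylab = "head capsule width (mm)", ...)
  graphics::abline(h = c(x$bins$small_upper, x$bins$large_lower), lty = 2,
                   col = "grey50")
  graphics::legend("topleft", legend = levels(sp), col = seq_along(levels(sp)),
                   pch = 19, bty = "n")
  invisible(x)
}
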