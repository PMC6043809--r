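#' PLFA biomarker groups
#'
#' The marker fatty acids used for community indices: Gram-positive
#' bacteria (iC15:0, aC15:0, iC16:0, iC17:0, aC17:0), Gram-negative
#' bacteria (cyC17:0, cyC19:0, C16:1c9, C18:1c11), actinobacteria
#' (10MeC16:0, 10MeC18:0), total bacteria (Gram-positive +
#' Gram-negative + C17:0) and saprotrophic fungi (C18:2c9,12).
#'
#' @return Named list of character vectors of fatty-acid names.
#' @export
#' @examples
#' plfaMarkerGroups()$fungi
plfaMarkerGroups <- function() {
  gp <- c("iC15:0", "aC15:0", "iC16:0", "iC17:0", "aC17:0")
  gn <- c("cyC17:0", "cyC19:0", "C16:1c9", "C18:1c11")
  list(gram_positive = gp,
       gram_negative = gn,
       actinobacteria = c("10MeC16:0", "10MeC18:0"),
       bacteria = c(gp, gn, "C17:0"),
       fungi = "C18:2c9,12")
}

#' Saturation class of a fatty acid from its name
#'
#' Classifies by the double-bond count in the shorthand name (the
#' number after the colon): 0 = saturated, 1 = mono-unsaturated, more =
#' poly-unsaturated. Cyclopropyl (cy-) and methyl-branched (10Me-, i-,
#' a-) acids carry no double bond and count as saturated.
#'
#' @param acids Character vector of fatty-acid names, e.g. "C16:1c9".
#' @return Character vector: "saturated", "monounsaturated" or
#'   "polyunsaturated".
#' @export
#' @examples
#' plfaSaturation(c("iC15:0", "C16:1c9", "C18:2c9,12"))
plfaSaturation <- function(acids) {
  m <- regmatches(acids, regexpr(":[0-9]+", acids))
  if (length(m) != length(acids) || any(!nzchar(m)))
    stop("unparseable fatty acid name(s)")
  bonds <- as.integer(substring(m, 2))
  ifelse(bonds == 0L, "saturated",
         ifelse(bonds == 1L, "monounsaturated", "polyunsaturated"))
}

# acid columns of a PLFA table (everything except sample_id)
.plfa_acids <- function(tab) setdiff(names(tab), "sample_id")

#' Abundance filter for PLFA tables
#'
#' Retains, per sample, only fatty acids representing more than
#' `thresholdPct` of that sample's total PLFA (strictly more: an acid
#' at exactly the threshold is dropped). Dropped concentrations are set
#' to zero, so the filter is idempotent: shares can only grow after a
#' pass, never shrink below the threshold.
#'
#' @param tab data.frame with a `sample_id` column and one
#'   concentration column per fatty acid (nmol g^-1).
#' @param thresholdPct Abundance threshold in percent (default 1).
#' @return The filtered table.
#' @export
filterPlfa <- function(tab, thresholdPct = 1) {
  acids <- .plfa_acids(tab)
  stopifnot(length(acids) > 0L)
  for (r in seq_len(nrow(tab))) {
    conc <- as.numeric(unlist(tab[r, acids]))
    tot <- sum(conc)
    if (tot <= 0) next
    drop <- 100 * conc / tot <= thresholdPct
    if (any(drop)) tab[r, acids[drop]] <- 0
  }
  tab
}

#' PLFA community indices
#'
#' Per sample: applies the abundance filter, sums the marker groups,
#' and computes the bacteria-to-fungi ratio (bacterial marker sum over
#' the fungal marker C18:2c9,12) and the nutrient-limitation index
#' (sum of saturated over sum of mono-unsaturated PLFAs, classified
#' from the acid names). Total PLFA is the sum over retained acids.
#'
#' @param tab data.frame: `sample_id` plus one column per fatty acid.
#' @param filter Apply the 1% abundance filter first (default TRUE).
#' @param thresholdPct Filter threshold, percent.
#' @return data.frame with one row per sample: total_plfa, group sums,
#'   bf_ratio (NA with `bf_defined = FALSE` when the fungal marker is
#'   absent after filtering), saturation_index.
#' @export
plfaIndices <- function(tab, filter = TRUE, thresholdPct = 1) {
  stopifnot(nrow(tab) > 0L)
  if (filter) tab <- filterPlfa(tab, thresholdPct)
  acids <- .plfa_acids(tab)
  groups <- plfaMarkerGroups()
  satcls <- plfaSaturation(acids)
  rows <- lapply(seq_len(nrow(tab)), function(r) {
    conc <- setNames(as.numeric(unlist(tab[r, acids])), acids)
    gsum <- vapply(groups, function(g)
      sum(conc[intersect(g, acids)]), numeric(1))
    fungal <- gsum[["fungi"]]
    bf <- if (fungal > 0) gsum[["bacteria"]] / fungal else NA_real_
    sat <- sum(conc[satcls == "saturated"])
    mono <- sum(conc[satcls == "monounsaturated"])
    data.frame(sample_id = tab$sample_id[r],
               total_plfa = sum(conc),
               gram_positive = gsum[["gram_positive"]],
               gram_negative = gsum[["gram_negative"]],
               actinobacteria = gsum[["actinobacteria"]],
               bacteria = gsum[["bacteria"]],
               fungi = fungal,
               bf_ratio = bf, bf_defined = fungal > 0,
               saturation_index = if (mono > 0) sat / mono else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (any(!out$bf_defined))
    warning("fungal marker absent after filtering in some samples: B:F undefined")
  out
}

#' Synthetic PLFA table with known group totals
#'
#' Distributes requested totals for Gram-positive, Gram-negative,
#' actinobacteria, the generalist C17:0 and fungi equally over their
#' marker acids (so group sums reproduce the inputs exactly before
#' noise), and adds one trace acid below the 1% abundance threshold to
#' exercise the filter.
#'
#' @param groupTotals Named numeric: `gram_positive`, `gram_negative`,
#'   `actinobacteria`, `c17`, `fungi` (nmol g^-1).
#' @param nSamples Number of identically parameterized samples.
#' @param noiseSd Gaussian noise s.d. per acid (truncated at 0).
#' @param traceFraction Share of the grand total given to the trace
#'   acid C15:0 (default 0.005, i.e. 0.5%).
#' @param seed RNG seed.
#' @return data.frame: `sample_id` plus one column per acid; truth
#'   (group sums, B:F, trace acid) in `attr(x, "truth")`.
#' @export
generatePlfaTable <- function(groupTotals = c(gram_positive = 30,
                                              gram_negative = 20,
                                              actinobacteria = 8,
                                              c17 = 3, fungi = 10),
                              nSamples = 1L, noiseSd = 0,
                              traceFraction = 0.005, seed = 1L) {
  stopifnot(all(groupTotals >= 0), traceFraction >= 0, traceFraction < 1)
  need <- c("gram_positive", "gram_negative", "actinobacteria", "c17",
            "fungi")
  stopifnot(all(need %in% names(groupTotals)))
  set.seed(seed)
  g <- plfaMarkerGroups()
  conc <- c(setNames(rep(groupTotals[["gram_positive"]] / length(g$gram_positive),
                         length(g$gram_positive)), g$gram_positive),
            setNames(rep(groupTotals[["gram_negative"]] / length(g$gram_negative),
                         length(g$gram_negative)), g$gram_negative),
            setNames(rep(groupTotals[["actinobacteria"]] / 2, 2),
                     g$actinobacteria),
            "C17:0" = groupTotals[["c17"]],
            setNames(groupTotals[["fungi"]], g$fungi))
  total <- sum(conc)
  trace <- if (traceFraction > 0)
    traceFraction / (1 - traceFraction) * total else 0
  conc <- c(conc, "C15:0" = trace)
  rows <- lapply(seq_len(nSamples), function(s) {
    x <- conc
    if (noiseSd > 0) x <- pmax(x + rnorm(length(x), 0, noiseSd), 0)
    as.data.frame(c(list(sample_id = sprintf("S%02d", s)), as.list(x)),
                  check.names = FALSE, optional = TRUE)
  })
  out <- do.call(rbind, rows)
  bacteria <- groupTotals[["gram_positive"]] + groupTotals[["gram_negative"]] +
    groupTotals[["c17"]]
  attr(out, "truth") <- list(
    group_totals = groupTotals,
    bacteria = bacteria,
    bf_ratio = if (groupTotals[["fungi"]] > 0)
      bacteria / groupTotals[["fungi"]] else NA_real_,
    trace_acid = "C15:0",
    trace_share = traceFraction)
  out
}
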