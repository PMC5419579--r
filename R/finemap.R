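#' Candidate region around a lead variant in genetic-map units
#'
#' Takes the lead's genetic-map position and extends `flank_cm` on each
#' side; bp bounds come from linear interpolation of the map, with the
#' terminal segment's rate extended beyond the map ends and bounds clipped
#' to the mapped extent.
#'
#' @param lead_pos_bp lead variant bp position (must lie on the map's
#'   chromosome).
#' @param map data.frame with `chr`, `pos_bp`, `cM` (>= 2 rows), e.g. from
#'   [panel_genetic_map()].
#' @param flank_cm flank size in cM on each side (default 0.1).
#' @param chromosome chromosome of the lead (default: the map's first).
#' @return a `Region` list: `chromosome`, `lead_pos_bp`, `cm_bounds`,
#'   `bp_bounds` (closed interval, clipped to the map).
#' @export
define_region <- function(lead_pos_bp, map, flank_cm = 0.1,
                          chromosome = NULL) {
  map <- as.data.frame(map)
  stopifnot(all(c("chr", "pos_bp", "cM") %in% names(map)))
  if (is.null(chromosome)) chromosome <- map$chr[1]
  map <- map[map$chr == chromosome, , drop = FALSE]
  if (nrow(map) < 2) stop("map needs >= 2 points on chromosome ", chromosome)
  map <- map[order(map$pos_bp), ]
  lead_cm <- .map_interp(lead_pos_bp, map$pos_bp, map$cM)
  cm_lo <- lead_cm - flank_cm
  cm_hi <- lead_cm + flank_cm
  bp_lo <- .map_interp_inv(cm_lo, map$pos_bp, map$cM)
  bp_hi <- .map_interp_inv(cm_hi, map$pos_bp, map$cM)
  bp_lo <- max(bp_lo, min(map$pos_bp))
  bp_hi <- min(bp_hi, max(map$pos_bp))
  structure(list(chromosome = chromosome, lead_pos_bp = lead_pos_bp,
                 cm_bounds = c(max(cm_lo, min(map$cM)), min(cm_hi, max(map$cM))),
                 bp_bounds = c(floor(bp_lo), ceiling(bp_hi))),
            class = "Region")
}

# piecewise-linear interpolation bp -> cM, terminal rate extended outside
.map_interp <- function(x, pos, cm) {
  stats::approx(pos, cm, xout = x, rule = 2)$y +
    ifelse(x < pos[1],
           (x - pos[1]) * (cm[2] - cm[1]) / (pos[2] - pos[1]),
           ifelse(x > pos[length(pos)],
                  (x - pos[length(pos)]) *
                    (cm[length(cm)] - cm[length(cm) - 1]) /
                    (pos[length(pos)] - pos[length(pos) - 1]), 0))
}

# inverse map cM -> bp; flat (zero-recombination) segments resolve to their
# left edge, terminal rates extended
.map_interp_inv <- function(y, pos, cm) {
  if (y <= cm[1]) {
    rate <- (cm[2] - cm[1]) / (pos[2] - pos[1])
    return(pos[1] + (y - cm[1]) / rate)
  }
  k <- length(cm)
  if (y >= cm[k]) {
    rate <- (cm[k] - cm[k - 1]) / (pos[k] - pos[k - 1])
    return(pos[k] + (y - cm[k]) / rate)
  }
  j <- findInterval(y, cm)
  if (cm[j + 1] == cm[j]) return(pos[j])
  pos[j] + (y - cm[j]) * (pos[j + 1] - pos[j]) / (cm[j + 1] - cm[j])
}

#' Single-causal posterior probabilities from z-scores
#'
#' Under the assumption of exactly one causal variant among the M variants
#' of a region, the posterior probability that variant j drives the
#' association is `exp(z_j^2 / 2) / sum_t exp(z_t^2 / 2)`. Computed stably
#' by subtracting the maximum exponent before exponentiation.
#'
#' @param z finite association z-scores over the region (M >= 1).
#' @return posterior probability vector summing to 1.
#' @export
posterior_probs <- function(z) {
  if (length(z) == 0) stop("empty region")
  if (any(!is.finite(z))) stop("z-scores must be finite")
  a <- z^2 / 2
  e <- exp(a - max(a))
  e / sum(e)
}

#' 99% credible set
#'
#' Ranks variants by posterior probability (ties broken by smaller bp
#' position) and adds them until the cumulative mass strictly exceeds
#' `level`. A set of at most `tractable_max` variants is flagged tractable.
#'
#' @param pp normalized posterior probabilities.
#' @param positions_bp bp positions, used for tie-breaking and the span;
#'   defaults to the index.
#' @param variant_ids optional identifiers.
#' @param level credible level (default 0.99); membership requires
#'   cumulative mass > level, strictly.
#' @param tractable_max largest tractable set size (default 20).
#' @return a `CredibleSet` list: `variants` (ordered by descending pp),
#'   `pp`, `cumulative`, `size`, `span_bp`, `tractable`, `lead_pp`.
#' @export
credible_set <- function(pp, positions_bp = seq_along(pp),
                         variant_ids = as.character(seq_along(pp)),
                         level = 0.99, tractable_max = 20L) {
  stopifnot(length(pp) >= 1, abs(sum(pp) - 1) < 1e-6)
  ord <- order(-pp, positions_bp)
  cum <- cumsum(pp[ord])
  size <- which(cum > level)[1]
  if (is.na(size)) size <- length(pp)   # numerical guard; mass sums to 1
  members <- ord[seq_len(size)]
  structure(list(variants = variant_ids[members],
                 pp = pp[members],
                 cumulative = cum[seq_len(size)],
                 size = size,
                 span_bp = max(positions_bp[members]) - min(positions_bp[members]),
                 tractable = size <= tractable_max,
                 lead_pp = pp[members[1]]),
            class = "CredibleSet")
}

#' @export
print.CredibleSet <- function(x, ...) {
  cat(sprintf("CredibleSet: %d variants (mass %.4f, span %s bp)%s, lead pp %.3f\n",
              x$size, x$cumulative[x$size],
              format(x$span_bp, big.mark = ","),
              if (x$tractable) " [tractable]" else "", x$lead_pp))
  invisible(x)
}

#' Credible sets across ancestry-specific and combined analyses
#'
#' Builds one credible set per analysis (e.g. the analysis ancestry alone,
#' the external ancestry alone, and their sample-size-weighted combination)
#' over a shared region, and summarizes sizes, spans and lead posteriors.
#' An analysis absent for the region is reported as missing rather than
#' failing.
#'
#' @param z_list named list of z-score vectors over the same region
#'   variants; `NULL` entries mark missing analyses.
#' @param positions_bp shared variant positions.
#' @param variant_ids shared variant identifiers.
#' @param level,tractable_max passed to [credible_set()].
#' @return list with `sets` (named list of `CredibleSet` or `NULL`) and
#'   `summary` (data.table: analysis, size, span_bp, lead_pp, tractable,
#'   missing) plus `combined_shrinks` (logical, `TRUE` when the combined
#'   analysis has the smallest set).
#' @export
compare_ancestry_sets <- function(z_list, positions_bp,
                                  variant_ids = as.character(seq_along(positions_bp)),
                                  level = 0.99, tractable_max = 20L) {
  stopifnot(is.list(z_list), length(z_list) >= 1)
  sets <- lapply(z_list, function(z) {
    if (is.null(z)) return(NULL)
    stopifnot(length(z) == length(positions_bp))
    credible_set(posterior_probs(z), positions_bp, variant_ids,
                 level = level, tractable_max = tractable_max)
  })
  summ <- data.table::rbindlist(lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (is.null(s))
      data.table::data.table(analysis = nm, size = NA_integer_,
                             span_bp = NA_real_, lead_pp = NA_real_,
                             tractable = NA, missing = TRUE)
    else
      data.table::data.table(analysis = nm, size = s$size,
                             span_bp = as.numeric(s$span_bp),
                             lead_pp = s$lead_pp, tractable = s$tractable,
                             missing = FALSE)
  }))
  sizes <- summ$size[!summ$missing]
  comb <- if ("combined" %in% summ$analysis && !summ$missing[summ$analysis == "combined"])
    summ$size[summ$analysis == "combined"] <= min(sizes) else NA
  list(sets = sets, summary = summ, combined_shrinks = comb)
}

#' Sample-size-weighted meta z-scores for combined-ancestry fine-mapping
#'
#' Convenience wrapper combining two aligned z-score vectors with
#' [samplesize_meta()] element-wise.
#'
#' @param z1,z2 aligned z-score vectors.
#' @param n1,n2 sample sizes (scalar or vector).
#' @return combined z-score vector.
#' @export
combine_z <- function(z1, z2, n1, n2) {
  n1 <- rep_len(n1, length(z1)); n2 <- rep_len(n2, length(z2))
  w1 <- sqrt(n1); w2 <- sqrt(n2)
  (w1 * z1 + w2 * z2) / sqrt(w1^2 + w2^2)
}
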