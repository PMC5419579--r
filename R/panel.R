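#' Haplotype panel
#'
#' A phased reference panel for one ancestry: a binary haplotype matrix with
#' physical (bp) and genetic-map (cM) coordinates and ref/alt alleles. Stands
#' in for a phased reference panel such as a 1000-Genomes ancestry subset,
#' and is the LD source for z-score imputation, conditional analysis and
#' fine-mapping.
#'
#' @param haplotypes integer matrix, H haplotypes x M variants, entries 0/1.
#'   H must be even so haplotypes can be paired into diploids.
#' @param positions_bp strictly increasing 1-based physical positions.
#' @param alleles data.frame or matrix with columns `ref`, `alt`
#'   (uppercase A/C/G/T), one row per variant.
#' @param cM non-decreasing genetic-map coordinate per variant. Defaults to
#'   a uniform 1 cM/Mb map so that 0.1 cM corresponds to 100 kb.
#' @param chromosome chromosome label (single value).
#' @param ancestry_label free-text ancestry tag.
#' @param variant_ids optional variant identifiers; defaults to
#'   `chr:pos:ref:alt`.
#'
#' @return An object of class `HaplotypePanel`.
#' @export
haplotype_panel <- function(haplotypes, positions_bp, alleles,
                            cM = NULL, chromosome = "1",
                            ancestry_label = "SYNTH",
                            variant_ids = NULL) {
  haplotypes <- as.matrix(haplotypes)
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype matrix entries must be 0 or 1")
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) %% 2L != 0L)
    stop("number of haplotypes must be even (diploid pairing)")
  m <- ncol(haplotypes)
  positions_bp <- as.integer(positions_bp)
  if (length(positions_bp) != m)
    stop("positions_bp length must match the number of variants")
  if (m > 1 && any(diff(positions_bp) <= 0))
    stop("positions_bp must be strictly increasing")
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  if (!all(c("ref", "alt") %in% names(alleles)))
    stop("alleles needs 'ref' and 'alt' columns")
  alleles$ref <- toupper(alleles$ref)
  alleles$alt <- toupper(alleles$alt)
  ok <- alleles$ref %in% c("A", "C", "G", "T") &
    alleles$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("alleles must be single uppercase A/C/G/T bases")
  if (is.null(cM)) cM <- positions_bp * 1e-6
  if (length(cM) != m) stop("cM length must match the number of variants")
  if (m > 1 && any(diff(cM) < 0)) stop("cM must be non-decreasing")
  if (is.null(variant_ids))
    variant_ids <- paste(chromosome, positions_bp, alleles$ref, alleles$alt,
                         sep = ":")
  structure(
    list(haplotypes = haplotypes,
         positions_bp = positions_bp,
         alleles = alleles[, c("ref", "alt")],
         cM = as.numeric(cM),
         chromosome = as.character(chromosome)[1],
         ancestry_label = ancestry_label,
         variant_ids = as.character(variant_ids)),
    class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf(
    "HaplotypePanel [%s]: %d haplotypes x %d variants, chr %s, %s-%s bp (%.3f-%.3f cM)\n",
    x$ancestry_label, nrow(x$haplotypes), ncol(x$haplotypes), x$chromosome,
    format(min(x$positions_bp), big.mark = ","),
    format(max(x$positions_bp), big.mark = ","),
    min(x$cM), max(x$cM)))
  invisible(x)
}

#' @export
dim.HaplotypePanel <- function(x) dim(x$haplotypes)

#' Alternate-allele frequencies of a panel
#'
#' @param panel a `HaplotypePanel`.
#' @return numeric vector of alt-allele frequencies.
#' @export
panel_freq <- function(panel) colMeans(panel$haplotypes)

#' Subset a panel to a variant index range
#'
#' @param panel a `HaplotypePanel`.
#' @param idx integer variant indices (kept in order).
#' @return a `HaplotypePanel` over the selected variants.
#' @export
panel_subset <- function(panel, idx) {
  idx <- sort(unique(as.integer(idx)))
  out <- haplotype_panel(panel$haplotypes[, idx, drop = FALSE],
                         panel$positions_bp[idx],
                         panel$alleles[idx, , drop = FALSE],
                         cM = panel$cM[idx],
                         chromosome = panel$chromosome,
                         ancestry_label = panel$ancestry_label,
                         variant_ids = panel$variant_ids[idx])
  if (!is.null(panel$target_freq)) out$target_freq <- panel$target_freq[idx]
  out
}

#' Simulate a haplotype panel with block-correlated sites
#'
#' Generates haplotypes by a first-order Markov copying process along sites:
#' with probability `rho` site j copies the same haplotype's allele at site
#' j-1, otherwise it draws a fresh Bernoulli at site j's target frequency.
#' Target frequencies are uniform on `[maf_low, maf_high]`. This produces
#' LD that decays geometrically with inter-site distance — enough local
#' correlation structure for imputation, conditional analysis and
#' fine-mapping, without a coalescent's cost.
#'
#' @param n_hap number of haplotypes (even, >= 2).
#' @param n_var number of variant sites (>= 1).
#' @param region_bp region length in bp; positions are drawn uniformly and
#'   deduplicated within it.
#' @param rho per-site copy probability in `[0, 1]`; 0 gives independent
#'   sites, values near 1 give long LD blocks.
#' @param maf_low,maf_high bounds of the target allele-frequency draw,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed integer seed; the same arguments and seed reproduce the panel
#'   bit-for-bit.
#' @param cm_per_mb genetic-map rate used for the cM coordinate (default 1).
#' @param chromosome,ancestry_label labels passed through to the panel.
#'
#' @return a `HaplotypePanel`.
#' @export
simulate_haplotypes <- function(n_hap, n_var, region_bp = 1e6, rho = 0.9,
                                maf_low = 0.05, maf_high = 0.5,
                                seed = 1L, cm_per_mb = 1,
                                chromosome = "1", ancestry_label = "SYNTH") {
  if (n_hap < 2 || n_var < 1) stop("n_hap >= 2 and n_var >= 1 required")
  if (n_hap %% 2L != 0L) stop("n_hap must be even")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pos <- sort(sample.int(max(region_bp, n_var), n_var, replace = FALSE))
  freq <- stats::runif(n_var, maf_low, maf_high)
  H <- matrix(0L, n_hap, n_var)
  H[, 1] <- stats::rbinom(n_hap, 1L, freq[1])
  if (n_var > 1) {
    for (j in 2:n_var) {
      copy <- stats::runif(n_hap) < rho
      fresh <- stats::rbinom(n_hap, 1L, freq[j])
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    }
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_var, replace = TRUE)
  # draw a non-complementary alt so panels are palindrome-free by default;
  # palindromic test cases are constructed explicitly where needed
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  alt <- vapply(ref, function(r)
    sample(setdiff(bases, c(r, comp[[r]])), 1L), character(1))
  out <- haplotype_panel(H, pos, data.frame(ref = ref, alt = alt),
                         cM = pos * cm_per_mb * 1e-6,
                         chromosome = chromosome,
                         ancestry_label = ancestry_label)
  out$target_freq <- freq
  out
}

#' Derive a drifted population from a source panel
#'
#' Applies Balding-Nichols drift: each variant's derived target frequency is
#' drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the source target
#' frequency p, so that across variants `Var(p' - p) = F p (1 - p)`. New
#' haplotypes are then resampled with the source panel's Markov mosaic
#' process (same `rho`) around the drifted frequencies, giving a second
#' ancestry with shifted frequencies and its own LD realisation over the
#' same variants. The drawn frequencies are kept in the result's
#' `target_freq` field (the realized panel frequencies additionally carry
#' mosaic and finite-panel sampling noise).
#'
#' @param panel source `HaplotypePanel`.
#' @param fst Wright's fixation index F in `[0, 1)`; 0 returns frequencies
#'   unchanged.
#' @param seed integer seed.
#' @param rho copy probability for the resampled haplotypes (default 0.9).
#' @param n_hap number of derived haplotypes (default: same as source).
#' @param ancestry_label label for the derived panel.
#'
#' @return a `HaplotypePanel` with the same variants and positions.
#' @export
drift_population <- function(panel, fst, seed = 1L, rho = 0.9,
                             n_hap = nrow(panel$haplotypes),
                             ancestry_label = paste0(panel$ancestry_label, "_DRIFT")) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  if (fst >= 1 || fst < 0) stop("fst must be in [0, 1)")
  if (n_hap %% 2L != 0L) stop("n_hap must be even")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- if (!is.null(panel$target_freq)) panel$target_freq else panel_freq(panel)
  if (fst == 0) {
    p2 <- p
  } else {
    # Beta degenerates at p as F -> 0; monomorphic sites stay fixed
    a <- p * (1 - fst) / fst
    b <- (1 - p) * (1 - fst) / fst
    p2 <- ifelse(p <= 0 | p >= 1, p, stats::rbeta(length(p), a, b))
  }
  m <- ncol(panel$haplotypes)
  H <- matrix(0L, n_hap, m)
  H[, 1] <- stats::rbinom(n_hap, 1L, p2[1])
  if (m > 1) {
    for (j in 2:m) {
      copy <- stats::runif(n_hap) < rho
      fresh <- stats::rbinom(n_hap, 1L, p2[j])
      H[, j] <- ifelse(copy, H[, j - 1L], fresh)
    }
  }
  out <- haplotype_panel(H, panel$positions_bp, panel$alleles,
                         cM = panel$cM, chromosome = panel$chromosome,
                         ancestry_label = ancestry_label,
                         variant_ids = panel$variant_ids)
  out$target_freq <- p2
  out
}

#' LD correlation matrix from a haplotype panel
#'
#' Pearson correlation of allele indicators across haplotypes. Monomorphic
#' variants have zero variance; their correlations are set to 0 and the
#' diagonal to 1 so the matrix stays usable downstream.
#'
#' @param panel a `HaplotypePanel`.
#' @param idx optional variant indices (default: all).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
panel_ld <- function(panel, idx = NULL) {
  H <- panel$haplotypes
  if (!is.null(idx)) H <- H[, idx, drop = FALSE]
  sds <- apply(H, 2, stats::sd)
  R <- suppressWarnings(stats::cor(H))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  # guard tiny numerical excursions
  R[R > 1] <- 1; R[R < -1] <- -1
  (R + t(R)) / 2
}

#' Genetic map of a panel as a 3-column table
#'
#' @param panel a `HaplotypePanel`.
#' @return data.frame with columns `chr`, `pos_bp`, `cM`.
#' @export
panel_genetic_map <- function(panel) {
  data.frame(chr = panel$chromosome, pos_bp = panel$positions_bp,
             cM = panel$cM, stringsAsFactors = FALSE)
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
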