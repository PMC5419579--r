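#' Read a METAL-style summary-statistics table
#'
#' Tab-separated with header; mandatory columns `variant_id, chr, pos,
#' effect_allele, other_allele, beta, se, p, n` (plus `eaf`, `info`,
#' `direction` when present). Alleles are upper-cased; rows violating the
#' invariants (p outside (0,1], non-positive SE or N, duplicate variant
#' keys) are rejected into a line-numbered error report rather than
#' silently dropped.
#'
#' @param path file path.
#' @param required override the mandatory column set.
#' @return a `SumStatsTable` (data.table) with attribute `"rejected"`
#'   (data.table with `line` and `reason`).
#' @export
read_sumstats <- function(path,
                          required = c("variant_id", "chr", "pos",
                                       "effect_allele", "other_allele",
                                       "beta", "se", "p", "n")) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "chr"))
  missing_cols <- setdiff(required, names(ss))
  if (length(missing_cols))
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "))
  ss[, effect_allele := toupper(effect_allele)]
  ss[, other_allele := toupper(other_allele)]
  line <- seq_len(nrow(ss)) + 1L   # header is line 1
  reason <- rep(NA_character_, nrow(ss))
  if ("p" %in% names(ss))
    reason[is.na(reason) & (!is.finite(ss$p) | ss$p <= 0 | ss$p > 1)] <- "p_out_of_range"
  if ("se" %in% names(ss))
    reason[is.na(reason) & is.finite(ss$se) & ss$se <= 0] <- "nonpositive_se"
  if ("n" %in% names(ss))
    reason[is.na(reason) & is.finite(ss$n) & ss$n <= 0] <- "nonpositive_n"
  key <- paste(ss$chr, ss$pos, ss$effect_allele, ss$other_allele)
  reason[is.na(reason) & duplicated(key)] <- "duplicate_key"
  keep <- is.na(reason)
  rejected <- data.table::data.table(line = line[!keep],
                                     reason = reason[!keep])
  out <- ss[keep]
  data.table::setattr(out, "rejected", rejected)
  out
}

#' Write a summary-statistics table
#'
#' @param sumstats a `SumStatsTable`.
#' @param path output path (tab-separated, header).
#' @return the path, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  data.table::fwrite(data.table::as.data.table(sumstats), path, sep = "\t")
  invisible(path)
}

#' Export a haplotype panel as a phased VCF
#'
#' One diploid sample per consecutive haplotype pair, phased `GT` only.
#'
#' @param panel a `HaplotypePanel`.
#' @param path output `.vcf` path (plain text).
#' @return the path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  H <- panel$haplotypes
  n_s <- nrow(H) / 2
  samples <- sprintf("S%04d", seq_len(n_s))
  gt <- matrix("", ncol(H), n_s)
  for (s in seq_len(n_s))
    gt[, s] <- paste(H[2 * s - 1, ], H[2 * s, ], sep = "|")
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s>", panel$chromosome),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- apply(cbind(panel$chromosome, panel$positions_bp, panel$variant_ids,
                      panel$alleles$ref, panel$alleles$alt, ".", "PASS", ".",
                      "GT", gt), 1, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Import a phased VCF as a haplotype panel
#'
#' Reads phased `GT` fields into a binary haplotype matrix (two haplotypes
#' per sample). Multi-allelic records are skipped with a warning; an
#' unphased genotype is an error naming the record.
#'
#' @param path a plain-text VCF with phased genotypes.
#' @param cm_per_mb map rate for the cM coordinate (default 1).
#' @param ancestry_label label for the panel.
#' @return a `HaplotypePanel`.
#' @export
read_panel_vcf <- function(path, cm_per_mb = 1, ancestry_label = "VCF") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_panel_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) warning(sum(multi), " multi-allelic record(s) skipped")
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  unph <- which(matrix(grepl("/", gt, fixed = TRUE), nrow(gt)), arr.ind = TRUE)
  if (nrow(unph) > 0)
    stop(sprintf("unphased genotype at %s:%s",
                 fix[unph[1, 1], "CHROM"], fix[unph[1, 1], "POS"]))
  m <- nrow(fix); n_s <- ncol(gt)
  H <- matrix(0L, 2 * n_s, m)
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  H[seq(1, 2 * n_s, by = 2), ] <- t(matrix(as.integer(a1), m, n_s))
  H[seq(2, 2 * n_s, by = 2), ] <- t(matrix(as.integer(a2), m, n_s))
  chrom <- unique(fix[, "CHROM"])
  if (length(chrom) > 1) stop("panel import expects one chromosome")
  pos <- as.integer(fix[, "POS"])
  ids <- fix[, "ID"]
  haplotype_panel(H, pos, data.frame(ref = fix[, "REF"], alt = fix[, "ALT"]),
                  cM = pos * cm_per_mb * 1e-6, chromosome = chrom,
                  ancestry_label = ancestry_label,
                  variant_ids = ifelse(is.na(ids) | ids == ".", NA, ids))
}

#' Export a panel as a plain haplotype matrix plus site file
#'
#' Writes `<stem>.hap` (whitespace-delimited 0/1 matrix, one row per
#' haplotype) and `<stem>.sites` (3 columns: pos, ref, alt).
#'
#' @param panel a `HaplotypePanel`.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
write_panel_hap <- function(panel, stem) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  hap_path <- paste0(stem, ".hap")
  site_path <- paste0(stem, ".sites")
  utils::write.table(panel$haplotypes, hap_path, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(data.frame(panel$positions_bp, panel$alleles$ref,
                                panel$alleles$alt),
                     site_path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(c(hap_path, site_path))
}

#' Import a plain haplotype matrix plus site file
#'
#' @param stem path stem written by [write_panel_hap()].
#' @param cm_per_mb map rate for the cM coordinate (default 1).
#' @param chromosome,ancestry_label panel labels.
#' @return a `HaplotypePanel`.
#' @export
read_panel_hap <- function(stem, cm_per_mb = 1, chromosome = "1",
                           ancestry_label = "HAP") {
  H <- unname(as.matrix(utils::read.table(paste0(stem, ".hap"))))
  sites <- utils::read.table(paste0(stem, ".sites"),
                             col.names = c("pos", "ref", "alt"),
                             colClasses = c("integer", "character", "character"))
  haplotype_panel(H, sites$pos, sites[, c("ref", "alt")],
                  cM = sites$pos * cm_per_mb * 1e-6, chromosome = chromosome,
                  ancestry_label = ancestry_label)
}

#' Write a genetic map in 3-column format
#'
#' @param map data.frame with `chr`, `pos_bp`, `cM`.
#' @param path output path (tab-separated).
#' @return the path, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(all(c("chr", "pos_bp", "cM") %in% names(map)))
  data.table::fwrite(data.table::as.data.table(map)[, .(chr, pos_bp, cM)],
                     path, sep = "\t")
  invisible(path)
}

#' Read a 3-column genetic map
#'
#' @param path tab-separated file with columns `chr`, `pos_bp`, `cM`.
#' @return data.table sorted by chromosome and position.
#' @export
read_genetic_map <- function(path) {
  map <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = "chr"))
  stopifnot(all(c("chr", "pos_bp", "cM") %in% names(map)))
  map[order(chr, pos_bp)]
}
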