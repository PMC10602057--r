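#' Read GWAS summary statistics in the ldsc-style .sumstats dialect
#'
#' Parses a whitespace/tab-delimited text file with a header row containing
#' at least the columns `SNP`, `A1`, `A2`, `N`, `Z` (optionally `CHR`, `BP`,
#' `MAF`). Rows whose `Z` or `N` fail to parse as numbers are dropped with a
#' message; alleles are uppercased.
#'
#' @param path Path to the summary-statistics file.
#' @param phenotype_name Label attached to the returned records.
#' @return A data.frame with one row per SNP and columns `snp_id`, `chrom`,
#'   `bp`, `a1`, `a2`, `n`, `z`, `maf` (missing optional columns are `NA`),
#'   plus attribute `phenotype`.
#' @export
read_sumstats <- function(path, phenotype_name) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path)
  }
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "")
  names(raw) <- toupper(names(raw))
  required <- c("SNP", "A1", "A2", "N", "Z")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("summary-statistics schema error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    stop("empty input: no data rows in ", path)
  }
  z <- suppressWarnings(as.numeric(raw$Z))
  n <- suppressWarnings(as.numeric(raw$N))
  ok <- is.finite(z) & is.finite(n) & n > 0
  n_bad <- sum(!ok)
  if (n_bad > 0) {
    message(n_bad, " row(s) with non-numeric or non-positive Z/N dropped from ",
            path)
  }
  if (!any(ok)) {
    stop("empty input: zero parseable rows in ", path)
  }
  opt_num <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]])) else
      rep(NA_real_, nrow(raw))
  }
  rec <- data.frame(
    snp_id = raw$SNP,
    chrom  = as.integer(opt_num("CHR")),
    bp     = opt_num("BP"),
    a1     = toupper(raw$A1),
    a2     = toupper(raw$A2),
    n      = n,
    z      = z,
    maf    = opt_num("MAF"),
    stringsAsFactors = FALSE
  )[ok, , drop = FALSE]
  rownames(rec) <- NULL
  dup <- duplicated(rec$snp_id)
  if (any(dup)) {
    message(sum(dup), " duplicate rsID(s) dropped (first occurrence kept)")
    rec <- rec[!dup, , drop = FALSE]
  }
  attr(rec, "phenotype") <- phenotype_name
  rec
}

#' Read an LD-score table
#'
#' Expects whitespace/tab-delimited text with header columns `CHR`, `SNP`,
#' `BP`, `L2`. LD scores below 1 are invalid (a SNP's LD score includes its
#' own r-squared of 1) and raise an error.
#'
#' @param path Path to the LD-score file.
#' @return data.frame with columns `snp_id`, `chrom`, `bp`, `l2`.
#' @export
read_ldscores <- function(path) {
  if (!file.exists(path)) stop("LD-score file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- toupper(names(raw))
  need <- c("CHR", "SNP", "BP", "L2")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop("LD-score schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  out <- data.frame(snp_id = as.character(raw$SNP),
                    chrom = as.integer(raw$CHR),
                    bp = as.numeric(raw$BP),
                    l2 = as.numeric(raw$L2),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$snp_id)) stop("duplicate SNP ids in LD-score table")
  if (any(!is.finite(out$l2)) || any(out$l2 < 1)) {
    stop("invalid LD scores: every L2 must be finite and >= 1")
  }
  out
}

#' Write an LD-score table
#' @param ldscores data.frame as returned by [read_ldscores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ldscores <- function(ldscores, path) {
  out <- data.frame(CHR = ldscores$chrom, SNP = ldscores$snp_id,
                    BP = ldscores$bp, L2 = ldscores$l2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize per-phenotype summary statistics into an aligned panel
#'
#' Restricts to the SNP intersection across phenotypes and aligns every
#' phenotype's effect alleles to the reference phenotype's orientation:
#' when a phenotype carries the reference's alleles swapped, its Z sign is
#' flipped; strand-ambiguous palindromic SNPs (A/T, C/G) are dropped, as are
#' SNPs whose allele pair matches neither orientation.
#'
#' @param per_phenotype_records List of record data.frames from
#'   [read_sumstats()], one per phenotype.
#' @param phenotype_names Labels; default taken from each record set's
#'   `phenotype` attribute.
#' @param reference Index of the phenotype whose allele orientation is the
#'   shared reference (default 1).
#' @return A `sumstats_panel`: list with `snps` (data.frame `snp_id`,
#'   `chrom`, `bp`, `a1`, `a2`, `maf`), `z` and `n` (SNP-by-phenotype
#'   matrices) and `phenotypes`.
#' @export
harmonize_panel <- function(per_phenotype_records, phenotype_names = NULL,
                            reference = 1) {
  stopifnot(length(per_phenotype_records) >= 1)
  if (is.null(phenotype_names)) {
    phenotype_names <- vapply(seq_along(per_phenotype_records), function(i) {
      ph <- attr(per_phenotype_records[[i]], "phenotype")
      if (is.null(ph)) paste0("pheno", i) else ph
    }, character(1))
  }
  if (reference < 1 || reference > length(per_phenotype_records)) {
    stop("reference phenotype index out of range")
  }
  ids <- Reduce(intersect, lapply(per_phenotype_records, `[[`, "snp_id"))
  if (length(ids) == 0) stop("empty SNP intersection across phenotypes")

  ref <- per_phenotype_records[[reference]]
  ref <- ref[match(ids, ref$snp_id), , drop = FALSE]
  pal <- is_palindromic(ref$a1, ref$a2)
  if (any(pal)) {
    message(sum(pal), " palindromic SNP(s) dropped during harmonization")
  }
  keep <- !pal
  P <- length(per_phenotype_records)
  z <- matrix(NA_real_, length(ids), P)
  n <- matrix(NA_real_, length(ids), P)
  for (p in seq_len(P)) {
    rec <- per_phenotype_records[[p]]
    rec <- rec[match(ids, rec$snp_id), , drop = FALSE]
    same <- rec$a1 == ref$a1 & rec$a2 == ref$a2
    swap <- rec$a1 == ref$a2 & rec$a2 == ref$a1
    mismatch <- !(same | swap)
    if (any(mismatch & keep)) {
      message(sum(mismatch & keep), " SNP(s) with unresolvable alleles dropped (",
              phenotype_names[p], ")")
    }
    keep <- keep & !mismatch
    z[, p] <- ifelse(swap, -rec$z, rec$z)
    n[, p] <- rec$n
  }
  if (!any(keep)) stop("no SNPs survive harmonization")
  snps <- data.frame(snp_id = ref$snp_id, chrom = ref$chrom, bp = ref$bp,
                     a1 = ref$a1, a2 = ref$a2, maf = ref$maf,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(snps) <- NULL
  colnames(z) <- colnames(n) <- phenotype_names
  new_sumstats_panel(snps, z[keep, , drop = FALSE], n[keep, , drop = FALSE],
                     phenotype_names)
}

new_sumstats_panel <- function(snps, z, n, phenotypes) {
  structure(list(snps = snps, z = z, n = n, phenotypes = phenotypes),
            class = "sumstats_panel")
}

#' @export
print.sumstats_panel <- function(x, ...) {
  cat("sumstats_panel:", nrow(x$snps), "SNPs x", length(x$phenotypes),
      "phenotypes\n")
  cat("phenotypes:", paste(utils::head(x$phenotypes, 8), collapse = ", "),
      if (length(x$phenotypes) > 8) "..." else "", "\n")
  invisible(x)
}

#' Quality-control filter on an aligned panel
#'
#' Removes SNPs failing a minimum per-phenotype sample size or an absolute
#' Z cap in any phenotype.
#'
#' @param panel A `sumstats_panel`.
#' @param min_n Minimum per-SNP sample size (applied per phenotype).
#' @param max_abs_z Maximum |Z| allowed (default `Inf`, no cap).
#' @return Filtered `sumstats_panel`; errors if nothing survives.
#' @export
qc_filter <- function(panel, min_n = 0, max_abs_z = Inf) {
  stopifnot(inherits(panel, "sumstats_panel"), min_n >= 0, max_abs_z > 0)
  ok_n <- apply(panel$n >= min_n, 1, all)
  ok_z <- apply(abs(panel$z) <= max_abs_z, 1, all)
  keep <- ok_n & ok_z
  if (!any(keep)) stop("QC filter removed every SNP")
  subset_panel(panel, keep)
}

subset_panel <- function(panel, idx) {
  snps <- panel$snps[idx, , drop = FALSE]
  rownames(snps) <- NULL
  new_sumstats_panel(snps, panel$z[idx, , drop = FALSE],
                     panel$n[idx, , drop = FALSE], panel$phenotypes)
}

#' Write one phenotype of a panel back to the .sumstats dialect
#'
#' Round-trips with [read_sumstats()]: allele orientation and Z at full
#' precision are preserved.
#'
#' @param panel A `sumstats_panel`.
#' @param phenotype Phenotype label to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(panel, phenotype, path) {
  stopifnot(inherits(panel, "sumstats_panel"))
  if (nrow(panel$snps) == 0) stop("cannot write an empty panel")
  p <- match(phenotype, panel$phenotypes)
  if (is.na(p)) stop("unknown phenotype label: ", phenotype)
  out <- data.frame(SNP = panel$snps$snp_id,
                    CHR = panel$snps$chrom,
                    BP = panel$snps$bp,
                    A1 = panel$snps$a1,
                    A2 = panel$snps$a2,
                    MAF = panel$snps$maf,
                    N = panel$n[, p],
                    Z = format(panel$z[, p], digits = 17, trim = TRUE))
  if (all(is.na(out$MAF))) out$MAF <- NULL
  if (all(is.na(out$CHR))) { out$CHR <- NULL; out$BP <- NULL }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Restrict panel + LD scores to their shared SNPs, in panel order.
join_panel_ldscores <- function(panel, ldscores) {
  idx <- match(panel$snps$snp_id, ldscores$snp_id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("panel and LD-score table share no SNPs")
  list(panel = subset_panel(panel, keep), l2 = ldscores$l2[idx[keep]])
}
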