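#' @title Region-set overlap statistics
#' @name overlap_stats
#' @description
#' Dice-coefficient overlap between a factor's region set and any other
#' parcellation of the same universe, with a permutation null that redraws
#' the network's regions uniformly from the universe, and Benjamini-
#' Hochberg FDR adjustment across a batch of comparisons.
NULL

normalize_region <- function(x) {
  gsub("[ _\\-]", "", tolower(trimws(x)))
}

#' Construct a region set against a declared universe
#'
#' Region names are matched case-insensitively, ignoring whitespace,
#' underscores and hyphens; unknown names are an error, never a silent
#' drop.
#'
#' @param name Set label.
#' @param regions Character vector of region names (non-empty, no
#'   duplicates after normalization).
#' @param universe Character vector of all valid region names.
#' @param weights Optional per-region sizes (named by region or aligned
#'   with `regions`) for weighted Dice.
#' @return A `region_set`: list with `name`, `regions` (canonical universe
#'   spelling), `universe`, `weights`.
#' @export
region_set <- function(name, regions, universe, weights = NULL) {
  stopifnot(length(regions) > 0, length(universe) > 0)
  uni_norm <- normalize_region(universe)
  if (anyDuplicated(uni_norm)) stop("universe has duplicate region names")
  idx <- match(normalize_region(regions), uni_norm)
  if (anyNA(idx)) {
    stop("unknown region name(s): ",
         paste(regions[is.na(idx)], collapse = ", "))
  }
  idx <- unique(idx)
  w <- NULL
  if (!is.null(weights)) {
    if (!is.null(names(weights))) {
      w <- weights[match(uni_norm[idx], normalize_region(names(weights)))]
    } else {
      stopifnot(length(weights) == length(regions))
      w <- weights[!duplicated(idx)]
    }
    if (anyNA(w) || any(w <= 0)) stop("invalid region weights")
  }
  structure(list(name = name, regions = universe[idx], universe = universe,
                 weights = w),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set '", x$name, "' (", length(x$regions), " of ",
      length(x$universe), " regions)\n", sep = "")
  cat(" ", paste(x$regions, collapse = ", "), "\n")
  invisible(x)
}

#' Dice coefficient between two region sets
#'
#' Unweighted: 2|A intersect B| / (|A| + |B|). With per-region weights,
#' sizes are replaced by weight sums: 2 sum_{A^B} w / (sum_A w + sum_B w).
#'
#' @param a,b `region_set` objects on the same universe.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  if (!setequal(a$universe, b$universe)) {
    stop("region sets live on different universes")
  }
  inter <- intersect(a$regions, b$regions)
  if (is.null(a$weights) && is.null(b$weights)) {
    return(2 * length(inter) / (length(a$regions) + length(b$regions)))
  }
  wa <- if (is.null(a$weights)) rep(1, length(a$regions)) else a$weights
  wb <- if (is.null(b$weights)) rep(1, length(b$regions)) else b$weights
  names(wa) <- a$regions; names(wb) <- b$regions
  w_univ <- wa[!duplicated(names(wa))]
  2 * sum(w_univ[intersect(names(w_univ), inter)], na.rm = TRUE) /
    (sum(wa) + sum(wb))
}

#' Permutation p-value for a network/parcel Dice coefficient
#'
#' The null repopulates the network with |network| regions drawn uniformly
#' without replacement from the universe, holding the parcel fixed, and
#' recomputes the Dice coefficient each iteration. The reported p is the
#' add-one Monte-Carlo estimate (1 + #{null >= observed}) / (1 + n_iter),
#' never exactly zero, and is reproducible given the seed.
#'
#' @param network,parcel `region_set` objects on the same universe.
#' @param n_iter Number of permutations (default 1000).
#' @param seed Integer seed for the draws.
#' @return An `overlap_result`: `pair`, `dice`, `p_perm`, `q_fdr` (NA until
#'   batch adjustment), `n_iter`, `seed`.
#' @export
permutation_pvalue <- function(network, parcel, n_iter = 1000, seed = 1) {
  stopifnot(inherits(network, "region_set"), inherits(parcel, "region_set"))
  universe <- network$universe
  k <- length(network$regions)
  if (k > length(universe)) stop("network larger than its universe")
  observed <- dice_coefficient(network, parcel)
  parcel_regions <- parcel$regions
  null_dice <- local({
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    vapply(seq_len(n_iter), function(i) {
      draw <- sample(universe, k)
      2 * length(intersect(draw, parcel_regions)) /
        (k + length(parcel_regions))
    }, numeric(1))
  })
  p <- (1 + sum(null_dice >= observed)) / (1 + n_iter)
  structure(list(pair = c(network = network$name, parcel = parcel$name),
                 dice = observed, p_perm = p, q_fdr = NA_real_,
                 n_iter = n_iter, seed = seed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap %s vs %s: Dice = %.3f, p_perm = %.4g (n_iter = %d, seed = %d)\n",
              x$pair[["network"]], x$pair[["parcel"]], x$dice, x$p_perm,
              x$n_iter, x$seed))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; length- and
#' order-preserving. Thin wrapper over [stats::p.adjust()] so every
#' multiple-testing correction in the pipeline goes through one surface.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Vector of q-values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Number of distinct regions covered by a collection of region sets
#'
#' @param sets List of `region_set` objects (or plain character vectors).
#' @return Size of the union.
#' @export
region_union_count <- function(sets) {
  if (length(sets) == 0) return(0L)
  regions <- unlist(lapply(sets, function(s) {
    if (inherits(s, "region_set")) s$regions else as.character(s)
  }))
  length(unique(normalize_region(regions)))
}

#' The 34 Desikan-Killiany cortical region names
#'
#' The bilateral gyral-anatomy parcellation whose regional surface-area and
#' thickness phenotypes define the factor universe.
#'
#' @return Character vector of 34 region names.
#' @export
dk_regions <- function() {
  path <- system.file("extdata", "desikan_killiany_34.txt",
                      package = "gibnet", mustWork = TRUE)
  readLines(path)
}

#' Published region sets of the latent brain networks
#'
#' The region lists of the six surface-area ("SA1".."SA6") and four
#' cortical-thickness ("CT1".."CT4") genetically informed brain networks,
#' as shipped in `inst/extdata`.
#'
#' @param which `"SA"` or `"CT"`.
#' @return Named list of `region_set` objects on the Desikan-Killiany
#'   universe.
#' @export
gibn_region_sets <- function(which = c("SA", "CT")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("gibn_", tolower(which), "_regions.tsv"),
                      package = "gibnet", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  universe <- dk_regions()
  sets <- split(tab$region, tab$set_name)
  sets <- sets[order(names(sets))]
  out <- lapply(names(sets), function(nm) region_set(nm, sets[[nm]], universe))
  names(out) <- names(sets)
  out
}

#' Read region sets from a two-column TSV
#'
#' @param path TSV with header columns `set_name` and `region`.
#' @param universe Character vector of valid region names.
#' @return Named list of `region_set` objects.
#' @export
read_region_sets <- function(path, universe) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("set_name", "region") %in% names(tab))) {
    stop("region-set file needs columns set_name, region")
  }
  sets <- split(tab$region, tab$set_name)
  out <- lapply(names(sets), function(nm) region_set(nm, sets[[nm]], universe))
  names(out) <- names(sets)
  out
}
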