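# Greedy LD clumping of instruments against a supplied correlation matrix.

#' Construct an LD correlation matrix object
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param r Square numeric matrix of pairwise correlations (not squared),
#'   symmetric with unit diagonal, dimension `length(variant_ids)`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(variant_ids, r) {
  stopifnot(is.character(variant_ids), is.matrix(r))
  if (nrow(r) != length(variant_ids) || ncol(r) != length(variant_ids)) {
    stop("LD matrix dimension does not match the number of variants",
         call. = FALSE)
  }
  if (any(abs(r - t(r)) > 1e-8)) {
    stop("LD matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(r) - 1) > 1e-8)) {
    stop("LD matrix diagonal is not 1", call. = FALSE)
  }
  if (any(abs(r) > 1 + 1e-8)) {
    stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  }
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = variant_ids, r = r), class = "ld_matrix")
}

#' Read an LD matrix from text
#'
#' Two dialects are supported: `"matrix"`, a square tab-separated matrix
#' with variant identifiers as header row and first column; and `"long"`,
#' three tab-separated columns `id_a`, `id_b`, `r` (pairs not listed are
#' taken as uncorrelated; the diagonal is implied).
#'
#' @param path File path.
#' @param format `"matrix"` or `"long"`.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "matrix") {
    m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
    ld_matrix(rownames(m), as.matrix(m))
  } else {
    long <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    stopifnot(all(c("id_a", "id_b", "r") %in% names(long)))
    ids <- sort(unique(c(long$id_a, long$id_b)))
    r <- diag(length(ids))
    dimnames(r) <- list(ids, ids)
    for (i in seq_len(nrow(long))) {
      r[long$id_a[i], long$id_b[i]] <- long$r[i]
      r[long$id_b[i], long$id_a[i]] <- long$r[i]
    }
    ld_matrix(ids, r)
  }
}

# Deterministic candidate ordering: p-value, then chromosome, position, id.
.clump_order <- function(s) {
  order(s$pval, s$chromosome, s$position, s$variant_id, method = "radix")
}

#' Greedy LD clumping
#'
#' Iteratively selects the remaining variant with the smallest p-value as
#' an index variant and removes every other remaining variant on the same
#' chromosome within `window_bp` of it whose squared correlation with the
#' index exceeds `r2_threshold`. Ties on p-value are broken by chromosome,
#' then position, then identifier, so the result is invariant to input row
#' order.
#'
#' Variants absent from the LD matrix (or on different chromosomes) are
#' treated as uncorrelated; missing entries trigger a warning. The window
#' is one-sided: variants farther than `window_bp` from the index are kept
#' regardless of correlation.
#'
#' @param instruments A [sumstats] object (typically already filtered to
#'   genome-wide significance).
#' @param ld An [ld_matrix()] object, or `NULL` to treat all variants as
#'   independent.
#' @param r2_threshold Squared-correlation threshold (default 0.001).
#' @param window_bp Distance from the index variant, in base pairs, within
#'   which correlated variants are removed (default 10 Mb).
#' @return A [sumstats] object containing the index variants.
#' @export
greedy_clump <- function(instruments, ld = NULL, r2_threshold = 0.001,
                         window_bp = 1e7) {
  stopifnot(inherits(instruments, "sumstats"))
  if (!is.null(ld) && !inherits(ld, "ld_matrix")) {
    stop("'ld' must be an ld_matrix object or NULL", call. = FALSE)
  }
  s <- as.data.frame(instruments)
  if (nrow(s) <= 1) return(instruments)
  if (!is.null(ld)) {
    absent <- setdiff(s$variant_id, ld$variant_ids)
    if (length(absent) > 0) {
      warning(length(absent), " variant(s) absent from the LD matrix are",
              " treated as independent", call. = FALSE)
    }
  }
  ord <- .clump_order(s)
  remaining <- ord
  keep <- character(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    keep <- c(keep, s$variant_id[idx])
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- !is.na(s$chromosome[remaining]) &
      !is.na(s$chromosome[idx]) &
      s$chromosome[remaining] == s$chromosome[idx]
    in_window <- same_chr & !is.na(s$position[remaining]) &
      !is.na(s$position[idx]) &
      abs(s$position[remaining] - s$position[idx]) <= window_bp
    r2 <- rep(0, length(remaining))
    if (!is.null(ld)) {
      id_idx <- s$variant_id[idx]
      id_rem <- s$variant_id[remaining]
      present <- id_rem %in% ld$variant_ids & id_idx %in% ld$variant_ids
      if (any(present)) {
        r2[present] <- ld$r[id_idx, id_rem[present]]^2
      }
    }
    remaining <- remaining[!(in_window & r2 > r2_threshold)]
  }
  subset_sumstats(instruments, sort(match(keep, s$variant_id)))
}

#' Minimum-instrument-count rule
#'
#' Instruments with fewer than `min_variants` post-clumping variants are
#' considered too weak for analysis; ten or more pass.
#'
#' @param instruments A clumped [sumstats] object.
#' @param min_variants Minimum variant count (default 10).
#' @return `TRUE` iff the set has at least `min_variants` variants.
#' @export
count_rule <- function(instruments, min_variants = 10) {
  stopifnot(inherits(instruments, "sumstats"))
  nrow(instruments) >= min_variants
}
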