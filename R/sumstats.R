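# GWAS summary-statistic containers and instrument selection.

.canonical_cols <- c("variant_id", "chromosome", "position", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval", "n")
.mandatory_cols <- c("variant_id", "effect_allele", "other_allele",
                     "beta", "se", "pval")

#' Construct a GWAS summary-statistic set
#'
#' A `sumstats` object is a validated table of per-variant association
#' records from one GWAS: one row per variant, alleles coded so that `beta`
#' is the effect per copy of `effect_allele` (SD units for continuous
#' traits, log-odds for binary traits).
#'
#' Rows violating the record invariants (non-positive or non-finite `se`,
#' identical alleles, alleles outside A/C/G/T, `eaf` outside \[0, 1\],
#' `pval` outside (0, 1\], non-finite `beta`, duplicated `variant_id`) are
#' dropped; the number of dropped rows is stored in the `"n_dropped"`
#' attribute and reported via a message.
#'
#' @param data data.frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pval` and optionally `chromosome`,
#'   `position`, `eaf`, `n`.
#' @param trait_id Short identifier for the trait.
#' @param trait_label Human-readable label; defaults to `trait_id`.
#' @param trait_type One of `"continuous"`, `"binary-logistic"`,
#'   `"binary-linear"`; affects reporting only (binary effects are treated
#'   as log-odds throughout, with no liability-scale conversion).
#' @return An object of class `sumstats`: the validated data.frame with
#'   trait metadata attached as attributes.
#' @export
sumstats <- function(data, trait_id, trait_label = trait_id,
                     trait_type = c("continuous", "binary-logistic",
                                    "binary-linear")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data), is.character(trait_id), length(trait_id) == 1)
  missing_cols <- setdiff(.mandatory_cols, names(data))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(.canonical_cols, names(data))) data[[col]] <- NA
  data <- data[.canonical_cols]
  data$variant_id <- as.character(data$variant_id)
  data$chromosome <- as.character(data$chromosome)
  data$position <- suppressWarnings(as.integer(data$position))
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }
  data$n <- suppressWarnings(as.numeric(data$n))

  ok <- !is.na(data$variant_id) & nzchar(data$variant_id) &
    data$effect_allele %in% c("A", "C", "G", "T") &
    data$other_allele %in% c("A", "C", "G", "T") &
    data$effect_allele != data$other_allele &
    is.finite(data$beta) &
    is.finite(data$se) & data$se > 0 &
    is.finite(data$pval) & data$pval > 0 & data$pval <= 1 &
    (is.na(data$eaf) | (data$eaf >= 0 & data$eaf <= 1))
  ok[is.na(ok)] <- FALSE
  ok <- ok & !duplicated(data$variant_id)
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(trait_id, ": dropped ", n_dropped,
            " record(s) failing validation")
  }
  data <- data[ok, , drop = FALSE]
  rownames(data) <- NULL
  structure(data,
            trait_id = trait_id,
            trait_label = trait_label,
            trait_type = trait_type,
            n_dropped = n_dropped,
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat("GWAS summary statistics for '", attr(x, "trait_id"), "' (",
      attr(x, "trait_type"), "): ", nrow(x), " variant(s)\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

trait_id <- function(x) attr(x, "trait_id")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated (optionally gzip-compressed) table with a header
#' row and validates it into a [sumstats] object. Non-canonical column
#' names are handled through `column_map`.
#'
#' @param path Path to a TSV file (plain or `.gz`).
#' @param trait_id,trait_label,trait_type Passed to [sumstats()].
#' @param column_map Optional named character vector mapping canonical
#'   field names to the file's column names, e.g.
#'   `c(beta = "b", pval = "p")`.
#' @param sep Field separator, tab by default.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, trait_id, column_map = NULL,
                          trait_label = trait_id,
                          trait_type = "continuous", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           check.names = FALSE)
  if (nrow(raw) == 0) stop("empty summary-statistics file: ", path,
                           call. = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw)) {
        stop("column '", src, "' (mapped to '", canon, "') not found in ",
             path, call. = FALSE)
      }
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_cols <- setdiff(.mandatory_cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sumstats(raw, trait_id = trait_id, trait_label = trait_label,
           trait_type = trait_type)
}

#' Write a summary-statistic set to TSV
#'
#' @param x A [sumstats] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select genome-wide significant instruments
#'
#' Retains variants with `pval` strictly below `p_threshold` (the
#' conventional genome-wide significance level, 5e-8, by default).
#'
#' @param s A [sumstats] object.
#' @param p_threshold Significance threshold in (0, 1); strict `<`.
#' @return A [sumstats] object containing the significant subset (possibly
#'   empty).
#' @export
select_instruments <- function(s, p_threshold = 5e-8) {
  stopifnot(inherits(s, "sumstats"),
            is.numeric(p_threshold), p_threshold > 0, p_threshold < 1)
  keep <- s$pval < p_threshold
  subset_sumstats(s, keep)
}

# Subset a sumstats object preserving metadata attributes.
subset_sumstats <- function(s, i) {
  out <- as.data.frame(s)[i, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_id = attr(s, "trait_id"),
            trait_label = attr(s, "trait_label"),
            trait_type = attr(s, "trait_type"),
            class = c("sumstats", "data.frame"))
}
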