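#' Build a k-mer spectrum from a data frame of bin counts
#'
#' A k-mer spectrum is the histogram of distinct k-mers by multiplicity
#' (the number of times each k-mer occurs in a read set). `kmer_spectrum()`
#' validates a two-column data frame of `multiplicity` and `count`, fills
#' gaps with zero-count bins so that the spectrum is dense from multiplicity
#' 1 (or the smallest retained bin after windowing) up to the largest
#' observed multiplicity, and attaches the k-mer length as metadata.
#'
#' @param data Data frame with integer columns `multiplicity` (>= 1) and
#'   `count` (>= 0). Multiplicities must be unique.
#' @param k K-mer length used to count (positive integer; conversions from
#'   block- to per-nucleotide statistics depend on it). Default 21, the
#'   usual choice for genome profiling.
#' @param label Free-text sample identifier.
#' @return A tibble of class `kmer_spectrum` with columns `multiplicity`
#'   and `count`, dense over the covered range, with attributes `k` and
#'   `label`.
#' @examples
#' kmer_spectrum(data.frame(multiplicity = c(1, 3), count = c(100, 10)))
#' @export
kmer_spectrum <- function(data, k = 21, label = "") {
  if (!is.data.frame(data) || !all(c("multiplicity", "count") %in% names(data))) {
    stop("`data` must be a data frame with columns `multiplicity` and `count`")
  }
  d <- as.numeric(data$multiplicity)
  n <- as.numeric(data$count)
  if (length(d) == 0L) stop("spectrum is empty: no bins")
  if (anyNA(d) || anyNA(n)) stop("spectrum contains missing values")
  if (any(d < 1) || any(d != floor(d))) {
    stop("multiplicities must be positive integers")
  }
  if (any(n < 0)) stop("counts must be non-negative")
  if (anyDuplicated(d)) {
    stop("duplicate multiplicity in spectrum: ", d[duplicated(d)][1L])
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    stop("`k` must be a single positive integer")
  }
  ord <- order(d)
  d <- d[ord]
  n <- n[ord]
  # dense representation over the covered range: zero-fill interior gaps
  lo <- min(d)
  hi <- max(d)
  full <- lo:hi
  counts <- numeric(length(full))
  counts[match(d, full)] <- n
  new_kmer_spectrum(tibble::tibble(multiplicity = full, count = counts),
                    k = as.integer(k), label = as.character(label))
}

new_kmer_spectrum <- function(df, k, label) {
  structure(df,
            k = k,
            label = label,
            class = c("kmer_spectrum", class(tibble::tibble())))
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("# k-mer spectrum (k = %d%s): %d bins [%d..%d], %s distinct k-mers\n",
              attr(x, "k"),
              if (nzchar(attr(x, "label"))) paste0(", ", attr(x, "label")) else "",
              nrow(x), min(x$multiplicity), max(x$multiplicity),
              format(sum(x$count), big.mark = ",", scientific = FALSE)))
  NextMethod()
}

#' K-mer length of a spectrum
#' @param spectrum A `kmer_spectrum`.
#' @return Integer k-mer length.
#' @export
spectrum_k <- function(spectrum) attr(spectrum, "k")

#' Total distinct k-mers and total k-mer occurrences
#'
#' `n_distinct_kmers()` is the sum of bin counts; `n_occurrences()` weights
#' each bin by its multiplicity, i.e. the total number of k-mer instances
#' in the read set represented by the spectrum.
#' @param spectrum A `kmer_spectrum`.
#' @return A single number.
#' @export
n_distinct_kmers <- function(spectrum) sum(spectrum$count)

#' @rdname n_distinct_kmers
#' @export
n_occurrences <- function(spectrum) sum(spectrum$multiplicity * spectrum$count)

#' Read a two-column k-mer histogram
#'
#' Reads the plain-text histograms written by the common k-mer counters:
#' `jellyfish histo` (space-separated) and `kmc_tools transform histogram`
#' (tab-separated). Each non-empty line holds a multiplicity and the number
#' of distinct k-mers observed at that multiplicity. Interior gaps are
#' zero-filled. Terminal overflow bins (a last multiplicity accumulating
#' everything larger) are kept as ordinary bins; window below them with
#' [spectrum_window()] before fitting.
#'
#' @param path Path to the histogram file (or a connection).
#' @param dialect One of `"auto"` (sniff separator), `"jellyfish"`, `"kmc"`.
#' @param k K-mer length the histogram was counted with.
#' @param label Sample identifier; defaults to the file name.
#' @return A [kmer_spectrum()].
#' @export
read_kmer_histogram <- function(path, dialect = c("auto", "jellyfish", "kmc"),
                                k = 21, label = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty histogram: ", paste(path, collapse = ""))
  split_re <- if (dialect == "kmc") "\t" else if (dialect == "jellyfish") " +" else "[ \t]+"
  fields <- strsplit(trimws(lines), split_re)
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L]
    stop(sprintf("malformed histogram line %d: expected 2 fields, found %d",
                 idx[bad], nf[bad]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop(sprintf("malformed histogram line %d: non-numeric field", idx[bad]))
  }
  if (anyDuplicated(m[, 1L])) {
    stop("duplicate multiplicity in histogram: ", m[duplicated(m[, 1L]), 1L][1L])
  }
  if (is.null(label)) label <- if (is.character(path)) basename(path) else ""
  kmer_spectrum(tibble::tibble(multiplicity = m[, 1L], count = m[, 2L]),
                k = k, label = label)
}

#' Write a k-mer spectrum as a two-column histogram
#'
#' Canonical output: one bin per line, ascending multiplicity, separated by
#' a single space (`jellyfish` dialect) or a tab (`kmc` dialect).
#' Reading the result back with [read_kmer_histogram()] reproduces the
#' spectrum exactly.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param path Output path (or writable connection).
#' @param dialect `"jellyfish"` (space) or `"kmc"` (tab).
#' @return Invisibly, `path`.
#' @export
write_kmer_histogram <- function(spectrum, path, dialect = c("jellyfish", "kmc")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (nrow(spectrum) == 0L || sum(spectrum$count) == 0) {
    stop("refusing to write an empty spectrum (no k-mers)")
  }
  sep <- if (dialect == "kmc") "\t" else " "
  writeLines(paste(format(spectrum$multiplicity, trim = TRUE, scientific = FALSE),
                   format(spectrum$count, trim = TRUE, scientific = FALSE),
                   sep = sep),
             path)
  invisible(path)
}

#' Restrict a spectrum to a multiplicity window
#'
#' Fitting excludes the low-multiplicity region, where sequencing-error
#' k-mers and contamination often conceal the 1x peak, and the
#' high-multiplicity region occupied by repeats. `spectrum_window()` drops
#' bins outside `[d_min, d_max]`; counts are dropped, never redistributed.
#'
#' @param spectrum A `kmer_spectrum`.
#' @param d_min,d_max Inclusive multiplicity bounds, `1 <= d_min <= d_max`.
#' @return The windowed `kmer_spectrum`.
#' @export
spectrum_window <- function(spectrum, d_min, d_max = Inf) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (!(d_min >= 1 && d_min <= d_max)) {
    stop("invalid window: need 1 <= d_min <= d_max, got [", d_min, ", ", d_max, "]")
  }
  keep <- spectrum$multiplicity >= d_min & spectrum$multiplicity <= d_max
  out <- spectrum[keep, , drop = FALSE]
  if (nrow(out) == 0L || sum(out$count) == 0) {
    stop("window [", d_min, ", ", d_max, "] excludes all k-mers")
  }
  new_kmer_spectrum(out, k = attr(spectrum, "k"), label = attr(spectrum, "label"))
}
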