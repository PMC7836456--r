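# Pooled-screen read deconvolution and per-guide depletion scores against
# the plasmid DNA pool.

#' Deconvolve pooled-screen reads into guide counts
#'
#' Assigns each read to at most one guide by matching its extracted 20-mer
#' against the library spacers. With `mismatches = 1`, reads failing the
#' exact match are assigned to a guide at Hamming distance 1 when that guide
#' is unique; reads matching more than one guide at distance 1 are discarded
#' as unassigned.
#'
#' @param fastq FASTQ path (optionally gzipped).
#' @param library Guide library data.frame with `guide_id` and `spacer`.
#' @param spacer_start 0-based fixed position of the spacer in the read, or
#'   -1 (default) to scan each read for the constant vector prefix `CACCG`
#'   and take the following 20-mer.
#' @param mismatches 0 (exact) or 1.
#' @return A list with `counts` (named integer vector over guide IDs),
#'   `unassigned` and `total`.
#' @export
deconvolve <- function(fastq, library, spacer_start = -1L, mismatches = 0L) {
  if (!mismatches %in% c(0L, 1L)) stop("mismatches must be 0 or 1")
  if (anyDuplicated(library$spacer)) stop("library spacers must be unique")
  reads <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fastq, format = "fastq")),
    error = function(e) stop("failed to parse FASTQ ", fastq, ": ",
                             conditionMessage(e)))
  total <- length(reads)
  if (spacer_start >= 0L) {
    extracted <- substr(reads, spacer_start + 1L, spacer_start + 20L)
  } else {
    pos <- regexpr("CACCG", reads, fixed = TRUE)
    extracted <- ifelse(pos > 0L,
                        substr(reads, pos + 5L, pos + 24L),
                        NA_character_)
  }
  extracted[!is.na(extracted) & nchar(extracted) != 20L] <- NA_character_
  idx <- match(extracted, library$spacer)
  if (mismatches == 1L) {
    todo <- which(is.na(idx) & !is.na(extracted))
    if (length(todo)) {
      env <- new.env(hash = TRUE, size = 2L * nrow(library))
      for (i in seq_len(nrow(library)))
        assign(library$spacer[i], i, envir = env)
      bases <- c("A", "C", "G", "T")
      for (r in todo) {
        hit <- integer()
        sp <- extracted[r]
        for (p in 1:20) {
          orig <- substr(sp, p, p)
          for (b in bases[bases != orig]) {
            v <- sp
            substr(v, p, p) <- b
            j <- mget(v, envir = env, ifnotfound = list(NULL))[[1L]]
            if (!is.null(j)) hit <- c(hit, j)
          }
        }
        hit <- unique(hit)
        if (length(hit) == 1L) idx[r] <- hit  # ambiguous -> stays unassigned
      }
    }
  }
  counts <- tabulate(idx, nbins = nrow(library))
  names(counts) <- library$guide_id
  list(counts = counts, unassigned = sum(is.na(idx)), total = total)
}

#' Read or write a guide count matrix as TSV
#'
#' The TSV has a `guide_id` column followed by one integer column per
#' sample.
#'
#' @param path TSV path.
#' @return Integer matrix (guides x samples) with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"guide_id" %in% names(df)) stop("counts TSV needs a guide_id column")
  m <- as.matrix(df[, setdiff(names(df), "guide_id"), drop = FALSE])
  rownames(m) <- df$guide_id
  storage.mode(m) <- "integer"
  validate_counts(m)
  m
}

#' @rdname read_counts_tsv
#' @param counts Integer count matrix.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs guide rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(counts)
}

#' Median-ratio size factors
#'
#' DESeq-style normalisation: each sample's factor is the median across
#' guides (restricted to guides with a positive geometric mean over samples)
#' of the ratio of its count to the guide's geometric mean; factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Integer count matrix (guides x samples).
#' @return Positive numeric vector of size factors, one per sample.
#' @export
size_factors_median_ratio <- function(counts) {
  validate_counts(counts)
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no guide has positive counts in every sample")
  ratios <- counts[use, , drop = FALSE] / exp(loggeo[use])
  sf <- apply(ratios, 2L, stats::median)
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Total-count size factors
#'
#' Alternative to [size_factors_median_ratio()]: column totals rescaled to
#' geometric mean 1.
#'
#' @param counts Integer count matrix.
#' @return Positive numeric vector of size factors.
#' @export
size_factors_total <- function(counts) {
  validate_counts(counts)
  tot <- colSums(counts)
  if (any(tot == 0)) stop("sample(s) with all-zero counts")
  sf <- tot / exp(mean(log(tot)))
  stats::setNames(sf, colnames(counts))
}

#' Per-guide log2 fold changes and depletion ranks versus the DNA pool
#'
#' For each requested sample, computes
#' `lfc = log2((count/sf + pc) / (count_ref/sf_ref + pc))` per guide and
#' assigns depletion ranks (most depleted = rank 1) with deterministic
#' tie-breaking by guide ID. `norm_rank = rank / n_guides`.
#'
#' @param counts Integer count matrix (guides x samples).
#' @param samples Sample columns to score; default all non-reference
#'   columns.
#' @param reference Name of the DNA-pool reference column.
#' @param pseudocount Added to normalised counts (default 1).
#' @param size_factors Optional named size factors; default median-ratio.
#' @return Long data.frame with columns `guide_id`, `sample_id`, `lfc`,
#'   `rank`, `norm_rank`, `mean_lfc` (per-guide mean over the scored
#'   samples).
#' @export
guide_lfc <- function(counts, samples = NULL, reference,
                      pseudocount = 1, size_factors = NULL) {
  validate_counts(counts)
  if (!reference %in% colnames(counts))
    stop("unknown reference sample: ", reference)
  if (is.null(samples)) samples <- setdiff(colnames(counts), reference)
  if (!all(samples %in% colnames(counts)))
    stop("unknown sample(s): ",
         paste(setdiff(samples, colnames(counts)), collapse = ", "))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (is.null(size_factors)) size_factors <- size_factors_median_ratio(counts)
  norm <- sweep(counts, 2L, size_factors[colnames(counts)], "/")
  G <- nrow(counts)
  gid <- rownames(counts)
  per_sample <- lapply(samples, function(s) {
    lfc <- log2((norm[, s] + pseudocount) / (norm[, reference] + pseudocount))
    rk <- integer(G)
    rk[order(lfc, gid)] <- seq_len(G)
    # norm_rank uses average ranks for ties so tied guides stay
    # exchangeable; the integer rank stays a strict 1..G permutation
    nr <- rank(lfc, ties.method = "average") / G
    data.frame(guide_id = gid, sample_id = s, lfc = lfc, rank = rk,
               norm_rank = nr, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  out <- do.call(rbind, per_sample)
  mean_lfc <- tapply(out$lfc, out$guide_id, mean)
  out$mean_lfc <- as.numeric(mean_lfc[out$guide_id])
  out
}
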