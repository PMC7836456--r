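# Promoter gain/loss calling from paired tumour/normal H3K4me3 signals.
#
# Coordinates are BED-style 0-based half-open throughout; a TSS is a single
# 0-based base position.

#' Read a promoter annotation from BED6
#'
#' One BED record per promoter-driven transcript isoform. The `name` field
#' packs `promoter_id;gene_id;label` separated by `;` (label optional, e.g.
#' "P1"/"P2"). The TSS is taken as the 5' end of the record with respect to
#' its strand.
#'
#' @param path Path to a BED6 file.
#' @return A data.frame with columns `promoter_id`, `gene_id`, `label`,
#'   `chrom`, `tss` (0-based) and `strand`.
#' @export
read_promoter_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("no records in ", path)
  nm <- strsplit(as.character(gr$name), ";", fixed = TRUE)
  pid <- vapply(nm, `[`, "", 1L)
  gid <- vapply(nm, function(x) if (length(x) >= 2L) x[2L] else NA_character_, "")
  lab <- vapply(nm, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-")))
    stop("promoter strand must be '+' or '-'")
  # BED start is 0-based; GRanges start is 1-based.
  tss <- ifelse(strand == "+",
                BiocGenerics::start(gr) - 1L,
                BiocGenerics::end(gr) - 1L)
  out <- data.frame(promoter_id = pid, gene_id = gid, label = lab,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    tss = as.integer(tss), strand = strand,
                    stringsAsFactors = FALSE)
  validate_promoters(out)
  out
}

#' Write a promoter table as BED6
#'
#' Inverse of [read_promoter_bed()]: emits one single-base record per
#' promoter at its TSS, with `promoter_id;gene_id;label` in the name field.
#'
#' @param promoters Promoter data.frame (see [read_promoter_bed()]).
#' @param path Output path.
#' @export
write_promoter_bed <- function(promoters, path) {
  validate_promoters(promoters)
  lab <- if ("label" %in% names(promoters)) promoters$label else NA_character_
  name <- paste(promoters$promoter_id, promoters$gene_id,
                ifelse(is.na(lab), "", lab), sep = ";")
  df <- data.frame(promoters$chrom, promoters$tss, promoters$tss + 1L,
                   name, 0L, promoters$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_promoters <- function(promoters) {
  need <- c("promoter_id", "gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(promoters))
  if (length(miss)) stop("promoter table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(promoters$promoter_id))
    stop("duplicated promoter_id in annotation")
  if (any(promoters$tss < 0)) stop("tss must be >= 0")
  if (any(!promoters$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(promoters)
}

#' Per-pair log2 fold change of tumour over normal signal
#'
#' @param tumour,normal Non-negative signal vectors, one value per
#'   tumour/normal pair, aligned by position.
#' @param pseudocount Positive value added to both signals before the ratio;
#'   default 1.
#' @return Numeric vector `log2((tumour + pc) / (normal + pc))`.
#' @export
compute_pair_log2fc <- function(tumour, normal, pseudocount = 1) {
  if (length(tumour) != length(normal))
    stop("tumour and normal signal vectors differ in length (",
         length(tumour), " vs ", length(normal), ")")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  if (any(tumour < 0, na.rm = TRUE) || any(normal < 0, na.rm = TRUE))
    stop("signals must be non-negative")
  # difference of logs, so swapping tumour and normal negates exactly
  log2(tumour + pseudocount) - log2(normal + pseudocount)
}

#' Call gained/lost/unaltered status from per-pair log2 fold changes
#'
#' A pair counts as gained when its log2 fold change is `>= fc_threshold`
#' and as lost when `<= -fc_threshold`. The promoter is called gained when
#' at least `min_pairs` pairs are gained and gained pairs outnumber lost
#' pairs (majority rule, so a promoter cannot be simultaneously gained and
#' lost); lost is symmetric; anything else is unaltered.
#'
#' @param log2fc Numeric vector of per-pair log2 fold changes.
#' @param fc_threshold Positive per-pair log2 fold-change cutoff (default 1,
#'   i.e. 2-fold).
#' @param min_pairs Minimum number of deregulated pairs required to call a
#'   promoter (default 2).
#' @return A list with `status` (one of "gained", "lost", "unaltered"),
#'   `n_gained_pairs` and `n_lost_pairs`.
#' @export
call_status <- function(log2fc, fc_threshold = 1, min_pairs = 2) {
  if (length(log2fc) == 0L) stop("empty log2fc vector")
  if (fc_threshold <= 0) stop("fc_threshold must be > 0")
  if (min_pairs < 1) stop("min_pairs must be >= 1")
  ng <- sum(log2fc >= fc_threshold, na.rm = TRUE)
  nl <- sum(log2fc <= -fc_threshold, na.rm = TRUE)
  status <- if (ng >= min_pairs && ng > nl) "gained"
            else if (nl >= min_pairs && nl > ng) "lost"
            else "unaltered"
  list(status = status, n_gained_pairs = ng, n_lost_pairs = nl)
}

#' Call promoter status for every promoter in a signal table
#'
#' @param signals Long-format signal table with columns `promoter_id`,
#'   `sample_id`, `tumour`, `normal` (one row per promoter and
#'   tumour/normal pair), as read from the signals TSV.
#' @param promoters Optional promoter table used to attach `gene_id`.
#' @param pseudocount,fc_threshold,min_pairs See [compute_pair_log2fc()] and
#'   [call_status()].
#' @return A promoter-call data.frame with columns `promoter_id`, `gene_id`,
#'   `status`, `mean_log2fc`, `n_gained_pairs`, `n_lost_pairs`, `n_pairs`.
#' @export
call_promoters <- function(signals, promoters = NULL, pseudocount = 1,
                           fc_threshold = 1, min_pairs = 2) {
  need <- c("promoter_id", "tumour", "normal")
  miss <- setdiff(need, names(signals))
  if (length(miss)) stop("signal table lacks columns: ",
                         paste(miss, collapse = ", "))
  sp <- split(signals, signals$promoter_id)
  rows <- lapply(sp, function(d) {
    l2 <- compute_pair_log2fc(d$tumour, d$normal, pseudocount)
    st <- call_status(l2, fc_threshold, min_pairs)
    data.frame(promoter_id = d$promoter_id[1L],
               status = st$status,
               mean_log2fc = mean(l2),
               n_gained_pairs = st$n_gained_pairs,
               n_lost_pairs = st$n_lost_pairs,
               n_pairs = length(l2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(promoters)) {
    out$gene_id <- promoters$gene_id[match(out$promoter_id,
                                           promoters$promoter_id)]
    out <- out[, c("promoter_id", "gene_id", "status", "mean_log2fc",
                   "n_gained_pairs", "n_lost_pairs", "n_pairs")]
  } else {
    out$gene_id <- NA_character_
  }
  out
}

#' Gate promoter calls by isoform expression to pick screen targets
#'
#' A promoter is selected for the screen when its status is not "unaltered"
#' and its isoform expression is at or above `min_fpkm` (boundary
#' inclusive). Promoters missing from the expression table are treated as
#' unexpressed (expression 0) and reported.
#'
#' @param calls Promoter-call table from [call_promoters()].
#' @param expression Optional data.frame with columns `promoter_id` and
#'   `fpkm`; if `calls` already has an `expression` column it is used when
#'   `expression` is NULL.
#' @param min_fpkm Minimum expression for selection (default 5 FPKM).
#' @return `calls` with `expression` and logical `selected` columns.
#' @export
select_screen_targets <- function(calls, expression = NULL, min_fpkm = 5) {
  if (!is.null(expression)) {
    expr <- expression$fpkm[match(calls$promoter_id, expression$promoter_id)]
  } else if ("expression" %in% names(calls)) {
    expr <- calls$expression
  } else {
    expr <- rep(NA_real_, nrow(calls))
  }
  n_missing <- sum(is.na(expr))
  if (n_missing > 0L)
    message(n_missing,
            " promoter(s) without expression values; treated as 0 FPKM")
  expr[is.na(expr)] <- 0
  calls$expression <- expr
  calls$selected <- calls$status != "unaltered" & expr >= min_fpkm
  message(sum(calls$selected), " of ", nrow(calls), " promoters selected")
  calls
}

#' Summarise a coverage track into per-promoter signals
#'
#' Sums `value * overlap_width` of bedGraph intervals over the window
#' `[tss - flank, tss + flank)` (0-based half-open) of each promoter, for
#' users starting from coverage tracks rather than precomputed signal
#' tables. Promoters on chromosomes absent from the track get signal 0 with
#' a warning.
#'
#' @param track A bedGraph file path or a GRanges with a numeric `score`.
#' @param promoters Promoter table (see [read_promoter_bed()]).
#' @param flank Half-window size in bp (default 500).
#' @return Numeric vector of signals, one per promoter row.
#' @export
aggregate_track_to_promoters <- function(track, promoters, flank = 500) {
  if (flank < 0) stop("flank must be >= 0")
  if (is.character(track)) {
    track <- tryCatch(rtracklayer::import(track, format = "bedGraph"),
                      error = function(e)
                        stop("failed to parse bedGraph: ",
                             conditionMessage(e)))
  }
  validate_promoters(promoters)
  sig <- numeric(nrow(promoters))
  if (length(track) == 0L) return(sig)
  seen <- as.character(unique(GenomicRanges::seqnames(track)))
  unseen <- setdiff(unique(promoters$chrom), seen)
  if (length(unseen))
    warning("promoter chromosome(s) absent from track: ",
            paste(unseen, collapse = ", "), "; signal set to 0")
  keep <- promoters$chrom %in% seen
  if (!any(keep)) return(sig)
  # window [tss - flank, tss + flank) in 0-based half-open -> 1-based closed
  win <- GenomicRanges::GRanges(
    promoters$chrom[keep],
    IRanges::IRanges(start = pmax(promoters$tss[keep] - flank + 1L, 1L),
                     end = promoters$tss[keep] + flank))
  hits <- GenomicRanges::findOverlaps(win, track)
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(win[S4Vectors::queryHits(hits)],
                                    track[S4Vectors::subjectHits(hits)])
    contrib <- BiocGenerics::width(ov) *
      track$score[S4Vectors::subjectHits(hits)]
    agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    sig[keep][as.integer(names(agg))] <- as.numeric(agg)
  }
  sig
}
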