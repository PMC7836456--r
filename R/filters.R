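# Post-score hit filtering: pan-essential exclusion, multi-cell-line
# intersection, bidirectional-promoter off-target flagging and the contrast
# against a non-transformed control line.

#' Read a pan-essential gene list
#'
#' One gene symbol per line; genes lethal in more than 90% of DepMap cell
#' lines are the intended content.
#'
#' @param path Text file path.
#' @return Character vector of gene IDs.
#' @export
read_pan_essential <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Flag pan-essential genes in a score or hit table
#'
#' Gene-level membership test against the pan-essential list. Case-mismatch
#' near-misses are reported but not flagged.
#'
#' @param scores Data.frame with a `gene_id` column.
#' @param pan_list Character vector of pan-essential gene IDs.
#' @return `scores` with a logical `pan_essential` column.
#' @export
flag_pan_essential <- function(scores, pan_list) {
  if (length(pan_list) == 0L) {
    warning("empty pan-essential list; no genes flagged")
    scores$pan_essential <- FALSE
    return(scores)
  }
  scores$pan_essential <- scores$gene_id %in% pan_list
  near <- !scores$pan_essential & !is.na(scores$gene_id) &
    tolower(scores$gene_id) %in% tolower(pan_list)
  if (any(near))
    message("case-mismatched pan-essential near-miss(es), not flagged: ",
            paste(unique(scores$gene_id[near]), collapse = ", "))
  scores
}

#' Intersect essentiality calls across cell lines
#'
#' Collects, per promoter, the cancer cell lines in which it scores at
#' `fdr <= fdr_cutoff`. The normal line (if named) is excluded from the
#' intersection count and recorded separately. Promoters absent from a
#' line's table count as not essential there (universes are unioned with a
#' message). Pan-essential genes are flagged and excluded from the hit
#' cascade but retained in the table.
#'
#' @param scores Named list of per-cell-line score tables from
#'   [score_transcripts()].
#' @param fdr_cutoff FDR threshold (default 0.1).
#' @param min_lines Minimum number of cancer lines for a multi-line hit
#'   (default 2).
#' @param normal Name of the normal-line entry in `scores`, or NULL.
#' @param pan_list Optional pan-essential gene IDs.
#' @return Hit table with one row per promoter essential somewhere:
#'   `promoter_id`, `gene_id`, `essential_in` (comma-separated lines),
#'   `n_lines`, `min_fdr`, `normal_line_essential`, `pan_essential`,
#'   `final_hit` (`n_lines >= min_lines` and not pan-essential).
#' @export
intersect_lines <- function(scores, fdr_cutoff = 0.1, min_lines = 2,
                            normal = NULL, pan_list = character()) {
  if (!length(scores)) stop("no score tables supplied")
  if (is.null(names(scores)) || any(!nzchar(names(scores))))
    stop("score tables must be named by cell line")
  gc_lines <- setdiff(names(scores), normal)
  if (!length(gc_lines)) stop("no cancer cell line scored")
  universe <- unique(unlist(lapply(scores, `[[`, "promoter_id")))
  sizes <- vapply(scores, nrow, 0L)
  if (length(unique(sizes)) > 1L ||
      any(vapply(scores, function(s)
        length(setdiff(universe, s$promoter_id)) > 0L, TRUE)))
    message("promoter universes differ across lines; ",
            "absent promoters treated as not essential")
  ess <- sapply(scores, function(s) {
    v <- s$essential_at <- s$fdr <= fdr_cutoff
    out <- stats::setNames(rep(FALSE, length(universe)), universe)
    out[s$promoter_id] <- v
    out
  })
  ess <- matrix(ess, nrow = length(universe),
                dimnames = list(universe, names(scores)))
  gene <- rep(NA_character_, length(universe))
  for (s in scores)
    gene[match(s$promoter_id, universe)] <- s$gene_id
  fdr_mat <- matrix(vapply(scores[gc_lines], function(s) {
    out <- stats::setNames(rep(NA_real_, length(universe)), universe)
    out[s$promoter_id] <- s$fdr
    out
  }, numeric(length(universe))), nrow = length(universe))
  min_fdr <- apply(fdr_mat, 1L, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  n_lines <- rowSums(ess[, gc_lines, drop = FALSE])
  normal_ess <- if (!is.null(normal)) ess[, normal] else rep(FALSE, length(universe))
  hits <- data.frame(
    promoter_id = universe, gene_id = gene,
    essential_in = vapply(seq_along(universe), function(i)
      paste(gc_lines[ess[i, gc_lines]], collapse = ","), ""),
    n_lines = as.integer(n_lines), min_fdr = min_fdr,
    normal_line_essential = as.logical(normal_ess),
    stringsAsFactors = FALSE)
  hits <- hits[hits$n_lines >= 1L | hits$normal_line_essential, ,
               drop = FALSE]
  if (length(pan_list)) hits <- flag_pan_essential(hits, pan_list)
  else hits$pan_essential <- FALSE
  hits$final_hit <- hits$n_lines >= min_lines & !hits$pan_essential
  rownames(hits) <- NULL
  hits
}

#' Flag hits with a bidirectional promoter partner
#'
#' CRISPRi guides near one TSS also silence any other TSS within roughly
#' 2 kb, so a hit adjacent to another promoter may score through its
#' neighbour. For each hit, the nearest other TSS on the same chromosome at
#' a TSS-to-TSS distance strictly below `max_distance` (strand-agnostic) is
#' recorded; when that partner's gene is pan-essential the hit is treated as
#' an off-target artefact and `final_hit` is cleared. Partners that are not
#' pan-essential only flag the hit for review. `max_distance = 0` disables
#' the filter. Hits on chromosomes absent from the annotation are retained
#' with `bidirectional_assessed = FALSE`.
#'
#' @param hits Hit table from [intersect_lines()].
#' @param all_tss Genome-wide promoter table (should include non-library
#'   TSSs).
#' @param max_distance Distance bound in bp, strict inequality (default
#'   2000).
#' @param pan_list Pan-essential gene IDs.
#' @return `hits` with `bidirectional_partner`, `partner_distance`,
#'   `partner_pan_essential`, `bidirectional_assessed` columns and
#'   `final_hit` updated.
#' @export
bidirectional_filter <- function(hits, all_tss, max_distance = 2000,
                                 pan_list = character()) {
  validate_promoters(all_tss)
  hits$bidirectional_partner <- NA_character_
  hits$partner_distance <- NA_integer_
  hits$partner_pan_essential <- FALSE
  hits$bidirectional_assessed <- TRUE
  if (!"final_hit" %in% names(hits)) hits$final_hit <- TRUE
  if (nrow(hits) == 0L || max_distance <= 0) return(hits)
  idx <- match(hits$promoter_id, all_tss$promoter_id)
  for (i in seq_len(nrow(hits))) {
    if (is.na(idx[i])) {
      hits$bidirectional_assessed[i] <- FALSE
      next
    }
    chrom <- all_tss$chrom[idx[i]]
    tss <- all_tss$tss[idx[i]]
    other <- all_tss[all_tss$chrom == chrom &
                       all_tss$promoter_id != hits$promoter_id[i], ,
                     drop = FALSE]
    if (nrow(other) == 0L) next
    d <- abs(other$tss - tss)
    j <- which.min(d)
    if (d[j] < max_distance) {
      hits$bidirectional_partner[i] <- other$promoter_id[j]
      hits$partner_distance[i] <- d[j]
      hits$partner_pan_essential[i] <- other$gene_id[j] %in% pan_list
      if (hits$partner_pan_essential[i]) hits$final_hit[i] <- FALSE
    }
  }
  hits
}

#' Prioritise hits against the normal-line contrast
#'
#' Orders hits by breadth of cancer-line essentiality (descending), then by
#' not scoring in the normal line, then by best FDR, and marks
#' `gc_selective = final_hit & !normal_line_essential`.
#'
#' @param hits Hit table (after [bidirectional_filter()]).
#' @param normal_scores Optional score table of the normal line used to
#'   refresh `normal_line_essential`.
#' @param fdr_cutoff FDR threshold applied to `normal_scores` (default 0.1).
#' @return The reordered hit table with a `gc_selective` column.
#' @export
contrast_normal <- function(hits, normal_scores = NULL, fdr_cutoff = 0.1) {
  if (!is.null(normal_scores)) {
    ness <- normal_scores$fdr[match(hits$promoter_id,
                                    normal_scores$promoter_id)] <= fdr_cutoff
    ness[is.na(ness)] <- FALSE
    hits$normal_line_essential <- ness
  }
  if (nrow(hits) == 0L) {
    hits$gc_selective <- logical()
    return(hits)
  }
  hits$gc_selective <- hits$final_hit & !hits$normal_line_essential
  ord <- order(-hits$n_lines, hits$normal_line_essential, hits$min_fdr,
               hits$promoter_id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Summarise the hit-filter cascade
#'
#' Counts at each filtering stage: promoters essential in at least one
#' cancer line (pan-essential excluded), in at least `min_lines` lines, with
#' a bidirectional partner, removed for a pan-essential partner, and
#' surviving as final hits.
#'
#' @param hits Hit table after [bidirectional_filter()].
#' @param min_lines Multi-line threshold used upstream (default 2).
#' @return Named integer vector of stage counts.
#' @export
hit_cascade <- function(hits, min_lines = 2) {
  non_pan <- !hits$pan_essential
  c(essential_any_line = sum(non_pan & hits$n_lines >= 1L),
    essential_multi_line = sum(non_pan & hits$n_lines >= min_lines),
    bidirectional_flagged = sum(non_pan & hits$n_lines >= min_lines &
                                  !is.na(hits$bidirectional_partner)),
    removed_pan_partner = sum(non_pan & hits$n_lines >= min_lines &
                                hits$partner_pan_essential),
    final_hits = sum(hits$final_hit))
}
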