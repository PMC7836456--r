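# CRISPRi sgRNA library design: candidate enumeration in a TSS window,
# genome-uniqueness filtering, per-promoter selection, control sets and
# oligo emission.

OLIGO_FLANK_5 <- "AGGCACTTGCTCGTACGACGCGTCTCACACCG"
OLIGO_FLANK_3 <- "GTTTCGAGACGTTAAGGTGCCGGGCCCACAT"

#' Load a genome from FASTA
#'
#' @param x A FASTA path or a [Biostrings::DNAStringSet].
#' @return A DNAStringSet.
#' @export
load_genome <- function(x) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  if (!methods::is(x, "DNAStringSet")) stop("genome must be FASTA or DNAStringSet")
  # FASTA headers may carry descriptions after the sequence name
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Enumerate candidate sgRNA spacers around a TSS
#'
#' Scans both genomic strands for 20-mers immediately 5' of an NGG PAM whose
#' anchor lies within `window` bp of the promoter's TSS. The anchor is the
#' PAM-proximal base of the protospacer (the base dCas9 occupies next to the
#' PAM); the offset is `anchor - tss` signed in transcript orientation, so
#' positive offsets are downstream of the TSS. Spacers containing characters
#' other than A/C/G/T are excluded. No uniqueness or composition filtering
#' is applied here; see [filter_candidates()].
#'
#' @param genome FASTA path or DNAStringSet.
#' @param promoter One-row promoter data.frame (`promoter_id`, `chrom`,
#'   `tss`, `strand`).
#' @param window Half-window in bp (default 150); candidates satisfy
#'   `-window <= offset <= window`.
#' @return A guide data.frame with columns `guide_id`, `spacer`, `chrom`,
#'   `pam_site` (0-based position of the N of NGG on the forward strand
#'   representation), `strand` (guide strand), `offset`,
#'   `target_promoter_id`.
#' @export
enumerate_candidates <- function(genome, promoter, window = 150) {
  if (window <= 0) stop("window must be > 0")
  genome <- load_genome(genome)
  chrom <- promoter$chrom[1L]
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  tss0 <- promoter$tss[1L]          # 0-based
  pstrand <- promoter$strand[1L]
  chrlen <- length(genome[[chrom]])
  # region (1-based, inclusive) wide enough for any protospacer+PAM whose
  # anchor falls in the window
  r1 <- max(1L, tss0 - window - 22L + 1L)
  r2 <- min(chrlen, tss0 + window + 23L + 1L)
  region <- as.character(Biostrings::subseq(genome[[chrom]], r1, r2))
  chars <- strsplit(region, "")[[1L]]
  n <- length(chars)
  loc2glob0 <- function(local) r1 - 1L + (local - 1L)  # local 1-based -> global 0-based

  res <- list()
  # + strand guides: protospacer [p-20, p-1], PAM N at p, GG at p+1,p+2
  gg <- which(chars[-n] == "G" & chars[-1L] == "G")    # local starts of GG
  for (g in gg) {
    p <- g - 1L
    if (p - 20L < 1L || p + 2L > n) next
    spacer <- substr(region, p - 20L, p - 1L)
    anchor0 <- loc2glob0(p - 1L)
    off <- if (pstrand == "+") anchor0 - tss0 else tss0 - anchor0
    if (off < -window || off > window) next
    if (grepl("[^ACGT]", spacer)) next
    res[[length(res) + 1L]] <- data.frame(
      spacer = spacer, pam_site = loc2glob0(p), strand = "+",
      offset = off, stringsAsFactors = FALSE)
  }
  # - strand guides: forward shows CCN at [p, p+2]; protospacer forward
  # [p+3, p+22]; spacer = revcomp; anchor is the base at p+3
  cc <- which(chars[-n] == "C" & chars[-1L] == "C")
  for (p in cc) {
    if (p + 22L > n) next
    fwd <- substr(region, p + 3L, p + 22L)
    if (grepl("[^ACGT]", fwd)) next
    spacer <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    anchor0 <- loc2glob0(p + 3L)
    off <- if (pstrand == "+") anchor0 - tss0 else tss0 - anchor0
    if (off < -window || off > window) next
    res[[length(res) + 1L]] <- data.frame(
      spacer = spacer, pam_site = loc2glob0(p + 2L), strand = "-",
      offset = off, stringsAsFactors = FALSE)
  }
  if (!length(res)) {
    out <- data.frame(guide_id = character(), spacer = character(),
                      chrom = character(), pam_site = integer(),
                      strand = character(), offset = integer(),
                      target_promoter_id = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, res)
  out$chrom <- chrom
  out$target_promoter_id <- promoter$promoter_id[1L]
  out$guide_id <- paste0(promoter$promoter_id[1L], ":", out$chrom, ":",
                         out$pam_site, out$strand)
  out <- out[order(out$pam_site, out$strand),
             c("guide_id", "spacer", "chrom", "pam_site", "strand",
               "offset", "target_promoter_id")]
  rownames(out) <- NULL
  out
}

#' Count exact genome matches of a spacer
#'
#' Exact 20/20 occurrences of the spacer or its reverse complement across
#' all genome sequences; a PAM is not required for counting. A spacer equal
#' to its own reverse complement is counted once per site.
#'
#' @param spacer A 20-character string over A/C/G/T.
#' @param genome FASTA path or DNAStringSet.
#' @return Integer match count.
#' @export
count_genome_matches <- function(spacer, genome) {
  if (grepl("[^ACGT]", spacer)) stop("spacer must be over A/C/G/T")
  genome <- load_genome(genome)
  fw <- sum(Biostrings::vcountPattern(spacer, genome))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer)))
  if (rc == spacer) return(fw)
  fw + sum(Biostrings::vcountPattern(rc, genome))
}

#' Count exact genome matches for many spacers at once
#'
#' Vectorised version of [count_genome_matches()] built on a preprocessed
#' pattern dictionary; used for whole-library uniqueness checks.
#'
#' @param spacers Character vector of equal-length A/C/G/T spacers.
#' @param genome FASTA path or DNAStringSet.
#' @return Integer vector of match counts, aligned with `spacers`.
#' @export
count_genome_matches_many <- function(spacers, genome) {
  if (length(spacers) == 0L) return(integer())
  if (any(grepl("[^ACGT]", spacers))) stop("spacers must be over A/C/G/T")
  genome <- load_genome(genome)
  ss <- Biostrings::DNAStringSet(spacers)
  rc <- Biostrings::reverseComplement(ss)
  pd <- Biostrings::PDict(c(ss, rc))
  cnt <- rowSums(Biostrings::vcountPDict(pd, genome))
  n <- length(spacers)
  hits <- cnt[seq_len(n)] + cnt[n + seq_len(n)]
  pal <- as.character(rc) == spacers
  hits[pal] <- cnt[seq_len(n)][pal]
  as.integer(hits)
}

#' Filter candidate guides for composition and genome uniqueness
#'
#' Drops spacers containing the Pol III terminator homopolymer TTTT (unless
#' `exclude_tttt = FALSE`) and keeps spacers matching the genome exactly
#' once (spacer or reverse complement).
#'
#' @param candidates Guide data.frame from [enumerate_candidates()].
#' @param genome FASTA path or DNAStringSet.
#' @param exclude_tttt Drop TTTT-containing spacers (default TRUE).
#' @return The filtered data.frame with a `genome_hits` column.
#' @export
filter_candidates <- function(candidates, genome, exclude_tttt = TRUE) {
  if (nrow(candidates) == 0L) {
    candidates$genome_hits <- integer()
    return(candidates)
  }
  if (exclude_tttt)
    candidates <- candidates[!grepl("TTTT", candidates$spacer, fixed = TRUE), ,
                             drop = FALSE]
  if (nrow(candidates) == 0L) {
    candidates$genome_hits <- integer()
    return(candidates)
  }
  candidates$genome_hits <- count_genome_matches_many(candidates$spacer, genome)
  out <- candidates[candidates$genome_hits == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the guides closest to the TSS
#'
#' Returns `min(n, available)` guides ordered by `|offset|` ascending, ties
#' broken by offset sign (positive before negative) then lexicographic
#' spacer, so selection is fully deterministic. A shortfall (fewer than `n`
#' candidates, e.g. in AT- or GC-rich promoters) produces a warning, not an
#' error.
#'
#' @param candidates Filtered guide data.frame (genome_hits == 1).
#' @param n Guides per promoter (default 6).
#' @return The selected rows, renumbered `<<promoter>>_sg1..n` when a target
#'   promoter is annotated.
#' @export
select_guides <- function(candidates, n = 6) {
  if (nrow(candidates) < n)
    warning("only ", nrow(candidates), " candidate guide(s) available for ",
            if (nrow(candidates)) candidates$target_promoter_id[1L] else "promoter",
            " (wanted ", n, ")")
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(abs(candidates$offset), candidates$offset < 0,
               candidates$spacer)
  out <- candidates[ord[seq_len(min(n, nrow(candidates)))], , drop = FALSE]
  if (!is.null(out$target_promoter_id) && !anyNA(out$target_promoter_id))
    out$guide_id <- paste0(out$target_promoter_id, "_sg", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

design_guides_for_promoters <- function(genome, promoters, window = 150,
                                        guides_per_promoter = 6,
                                        exclude_tttt = TRUE) {
  genome <- load_genome(genome)
  cand <- do.call(rbind, lapply(seq_len(nrow(promoters)), function(i)
    enumerate_candidates(genome, promoters[i, , drop = FALSE], window)))
  if (is.null(cand) || nrow(cand) == 0L) return(cand)
  if (exclude_tttt)
    cand <- cand[!grepl("TTTT", cand$spacer, fixed = TRUE), , drop = FALSE]
  # one batched uniqueness pass for the whole promoter set
  hits <- count_genome_matches_many(cand$spacer, genome)
  cand$genome_hits <- hits
  cand <- cand[hits == 1L, , drop = FALSE]
  out <- do.call(rbind, lapply(
    split(cand, factor(cand$target_promoter_id,
                       levels = promoters$promoter_id)),
    select_guides, n = guides_per_promoter))
  rownames(out) <- NULL
  out
}

#' Generate non-targeting negative-control spacers
#'
#' Rejection-samples random 20-mers with GC content in `gc_range` and no
#' TTTT run until they have zero exact genome matches. Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param n Number of controls.
#' @param genome FASTA path or DNAStringSet.
#' @param gc_range Allowed GC fraction (default `c(0.4, 0.6)`).
#' @param max_rounds Sampling rounds before giving up.
#' @return Character vector of `n` spacers.
#' @export
make_negative_controls <- function(n, genome, gc_range = c(0.4, 0.6),
                                   max_rounds = 100) {
  if (n == 0L) return(character())
  genome <- load_genome(genome)
  found <- character()
  for (round in seq_len(max_rounds)) {
    m <- max(2L * (n - length(found)), 20L)
    cand <- vapply(seq_len(m), function(i)
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
      "")
    gc <- vapply(strsplit(cand, ""), function(x) mean(x %in% c("G", "C")), 0)
    cand <- cand[gc >= gc_range[1L] & gc <= gc_range[2L] &
                   !grepl("TTTT", cand, fixed = TRUE)]
    cand <- setdiff(unique(cand), found)
    if (!length(cand)) next
    hits <- count_genome_matches_many(cand, genome)
    found <- c(found, cand[hits == 0L])
    if (length(found) >= n) return(found[seq_len(n)])
  }
  stop("could not generate ", n, " negative controls in ",
       max_rounds, " rounds")
}

#' Assemble the full screen library
#'
#' Designs targeting guides for every selected promoter, unaltered-isoform
#' control guides for the paired unaltered promoter of each targeted gene
#' when one exists, positive-control guides for essential-gene promoters,
#' and `n_negative` non-targeting negative controls.
#'
#' @param genome FASTA path or DNAStringSet.
#' @param promoters Full promoter table.
#' @param selected_ids Promoter IDs to target (e.g.
#'   `calls$promoter_id[calls$selected]`).
#' @param unaltered_ids Promoter IDs usable as unaltered-isoform controls
#'   (default: promoters of targeted genes not in `selected_ids`).
#' @param essential_ids Promoter IDs of core-essential positive-control
#'   genes.
#' @param n_negative Number of negative controls (default 0).
#' @param window,guides_per_promoter,exclude_tttt Design parameters.
#' @return A guide library data.frame (columns `guide_id`, `spacer`,
#'   `chrom`, `pam_site`, `strand`, `offset`, `target_promoter_id`,
#'   `gene_id`, `category`, `genome_hits`) with the design parameters in
#'   `attr(, "design_params")`.
#' @export
build_library <- function(genome, promoters, selected_ids,
                          unaltered_ids = NULL, essential_ids = character(),
                          n_negative = 0, window = 150,
                          guides_per_promoter = 6, exclude_tttt = TRUE) {
  genome <- load_genome(genome)
  validate_promoters(promoters)
  if (is.null(unaltered_ids)) {
    genes <- promoters$gene_id[match(selected_ids, promoters$promoter_id)]
    unaltered_ids <- promoters$promoter_id[
      promoters$gene_id %in% genes &
        !promoters$promoter_id %in% selected_ids &
        !promoters$promoter_id %in% essential_ids]
    no_partner <- genes[!genes %in% promoters$gene_id[
      promoters$promoter_id %in% unaltered_ids]]
    if (length(no_partner))
      message(length(unique(no_partner)),
              " targeted gene(s) have no unaltered partner promoter")
  }
  sets <- list(targeting = selected_ids, unaltered_control = unaltered_ids,
               positive_control = essential_ids)
  ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("promoter_id assigned to more than one library category: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  parts <- list()
  for (cat in names(sets)) {
    pid <- sets[[cat]]
    if (!length(pid)) next
    sub <- promoters[match(pid, promoters$promoter_id), , drop = FALSE]
    if (anyNA(sub$promoter_id))
      stop("unknown promoter_id in category ", cat)
    g <- design_guides_for_promoters(genome, sub, window,
                                     guides_per_promoter, exclude_tttt)
    if (is.null(g) || nrow(g) == 0L) next
    g$category <- cat
    parts[[cat]] <- g
  }
  lib <- do.call(rbind, parts)
  if (is.null(lib)) stop("no guides designed for any category")
  lib$gene_id <- promoters$gene_id[match(lib$target_promoter_id,
                                         promoters$promoter_id)]
  if (n_negative > 0L) {
    neg <- make_negative_controls(n_negative, genome)
    lib <- rbind(lib, data.frame(
      guide_id = sprintf("neg_%04d", seq_len(n_negative)),
      spacer = neg, chrom = NA_character_, pam_site = NA_integer_,
      strand = NA_character_, offset = NA_integer_,
      target_promoter_id = NA_character_, category = "negative_control",
      gene_id = NA_character_, genome_hits = 0L,
      stringsAsFactors = FALSE))
  }
  if (anyDuplicated(lib$spacer))
    lib <- lib[!duplicated(lib$spacer), , drop = FALSE]
  if (anyDuplicated(lib$guide_id))
    stop("duplicated guide_id in library")
  rownames(lib) <- NULL
  lib <- lib[, c("guide_id", "spacer", "chrom", "pam_site", "strand",
                 "offset", "target_promoter_id", "gene_id", "category",
                 "genome_hits")]
  attr(lib, "design_params") <- list(
    window = window, guides_per_promoter = guides_per_promoter,
    n_negative = n_negative, exclude_tttt = exclude_tttt)
  lib
}

#' Library composition by category
#'
#' @param library Guide library data.frame (needs a `category` column).
#' @return Named integer vector of guide counts per category.
#' @export
library_composition <- function(library) {
  if (!"category" %in% names(library)) stop("library lacks 'category'")
  tab <- table(library$category)
  stats::setNames(as.integer(tab), names(tab))
}

#' Emit the cloning oligo for a spacer
#'
#' Concatenates the fixed 5' (32 nt) and 3' (31 nt) PCR-handle/BsmBI flanks
#' around the 20-nt spacer, yielding an 83-character oligo, bit-exact.
#'
#' @param spacer A 20-character spacer.
#' @return The 83-character oligo string.
#' @export
emit_oligo <- function(spacer) {
  if (length(spacer) != 1L || nchar(spacer) != 20L)
    stop("spacer must be a single 20-character string")
  paste0(OLIGO_FLANK_5, spacer, OLIGO_FLANK_3)
}
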