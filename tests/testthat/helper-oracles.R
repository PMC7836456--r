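# Independent oracles used to cross-check the implementation. These are
# deliberately written with different machinery (regex scans, per-read
# loops, Monte-Carlo) than the functions they verify.

# Overlap-aware regex enumeration of PAM-adjacent 20-mers in a window.
# Returns a data.frame(spacer, pam_site, strand, offset) like
# enumerate_candidates(), built by scanning every position with lookahead
# regexes instead of the package's character-vector scan.
oracle_enumerate <- function(seqchar, tss0, pstrand, window = 150) {
  out <- list()
  # plus-strand guides: [20-mer][N]GG ; spacer at m..m+19 (1-based),
  # N at m+20, anchor (PAM-proximal base) at m+19
  m <- gregexpr("(?=([ACGT]{21}GG))", seqchar, perl = TRUE)[[1L]]
  if (m[1L] != -1L) for (s in as.integer(m)) {
    spacer <- substr(seqchar, s, s + 19L)
    anchor0 <- (s + 19L) - 1L
    off <- if (pstrand == "+") anchor0 - tss0 else tss0 - anchor0
    if (off >= -window && off <= window)
      out[[length(out) + 1L]] <- data.frame(
        spacer = spacer, pam_site = (s + 20L) - 1L, strand = "+",
        offset = off, stringsAsFactors = FALSE)
  }
  # minus-strand guides: CC[N][20-mer] on the forward strand
  m <- gregexpr("(?=(CC[ACGT]{21}))", seqchar, perl = TRUE)[[1L]]
  if (m[1L] != -1L) for (s in as.integer(m)) {
    fwd <- substr(seqchar, s + 3L, s + 22L)
    spacer <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(fwd)))
    anchor0 <- (s + 3L) - 1L
    off <- if (pstrand == "+") anchor0 - tss0 else tss0 - anchor0
    if (off >= -window && off <= window)
      out[[length(out) + 1L]] <- data.frame(
        spacer = spacer, pam_site = (s + 2L) - 1L, strand = "-",
        offset = off, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(spacer = character(), pam_site = integer(),
                      strand = character(), offset = integer()))
  df <- do.call(rbind, out)
  df[order(df$pam_site, df$strand), ]
}

# Brute-force overlap-aware occurrence count of spacer or its reverse
# complement in a character genome.
oracle_count_matches <- function(spacer, seqchars) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer)))
  pats <- unique(c(spacer, rc))
  sum(vapply(seqchars, function(s) {
    sum(vapply(pats, function(p) {
      m <- gregexpr(paste0("(?=", p, ")"), s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) 0L else length(m)
    }, 0L))
  }, 0L))
}

# Per-read linear-scan assignment with a Hamming-distance budget.
oracle_assign_reads <- function(extracted, spacers, mismatches = 0L) {
  vapply(extracted, function(r) {
    if (is.na(r) || nchar(r) != 20L) return(NA_integer_)
    rb <- strsplit(r, "")[[1L]]
    d <- vapply(spacers, function(s)
      sum(rb != strsplit(s, "")[[1L]]), 0L)
    hit <- which(d <= mismatches)
    if (length(hit) == 1L) hit else NA_integer_
  }, 0L, USE.NAMES = FALSE)
}

# Monte-Carlo estimate of the alpha-RRA rho statistic: for each eligible
# order statistic j, estimate Pr[at least j of n uniforms <= r(j)] from
# `draws` simulated rank sets and take the minimum.
oracle_rho_mc <- function(norm_ranks, alpha = 0.25, draws = 2e5) {
  r <- sort(norm_ranks)
  n <- length(r)
  U <- matrix(stats::runif(n * draws), nrow = n)
  elig <- which(r <= alpha)
  if (!length(elig)) return(list(rho = 1, se = 0))
  est <- se <- numeric(length(elig))
  for (k in seq_along(elig)) {
    j <- elig[k]
    p <- mean(colSums(U <= r[j]) >= j)
    est[k] <- p
    se[k] <- sqrt(max(p * (1 - p), 1 / draws) / draws)
  }
  i <- which.min(est)
  list(rho = est[i], se = se[i])
}

# write a minimal 4-line-per-record FASTQ
write_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), "")
  writeLines(as.vector(rbind(paste0("@read", seq_along(reads)),
                             reads, "+", qual)), path)
  path
}
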