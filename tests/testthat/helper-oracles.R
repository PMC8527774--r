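# Independent oracles used across the suite.  These deliberately take the
# naive route (direct formulas, all-pairs scans, exhaustive enumeration)
# and never share code with the package internals they check.

# direct evaluation of G_i = i/n - x_i/L with the G_0 = 0 sentinel
naive_g <- function(x, L) {
  x <- sort(x)
  n <- length(x)
  c(0, seq_len(n) / n - x / L)
}

# all-pairs max of G_j - G_i over 0 <= i < j <= n, ties to smallest i then j
naive_max_dg <- function(G) {
  n <- length(G) - 1L
  best <- -Inf
  bi <- bj <- NA_integer_
  for (i in 0:(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- G[j + 1L] - G[i + 1L]
      if (v > best) {
        best <- v; bi <- i; bj <- j
      }
    }
  }
  list(delta_g = best, i = bi, j = bj)
}

# exhaustive-enumeration p-value over all C(L, n) arrangements
naive_exact_p <- function(observed, L, n, tol = 1e-12) {
  combos <- utils::combn(L, n)
  hits <- 0L
  for (k in seq_len(ncol(combos))) {
    m <- naive_max_dg(naive_g(combos[, k], L))
    if (m$delta_g >= observed - tol) hits <- hits + 1L
  }
  hits / ncol(combos)
}

# brute-force pathway enumerator for codon changes, using the standard
# code table as the authority; recursion instead of precomputed
# permutation tables
aa_of <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

oracle_pathways <- function(a, b) {
  d <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  walk <- function(cur, remaining) {
    if (!length(remaining)) {
      return(list(list(syn = 0, nonsyn = 0, hit_stop = FALSE)))
    }
    out <- list()
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      step_syn <- aa_of(cur) == aa_of(nxt)
      stop_here <- aa_of(nxt) == "*" && nxt != b
      for (tail in walk(nxt, setdiff(remaining, pos))) {
        out[[length(out) + 1L]] <- list(
          syn = tail$syn + as.integer(step_syn),
          nonsyn = tail$nonsyn + as.integer(!step_syn),
          hit_stop = tail$hit_stop || stop_here)
      }
    }
    out
  }
  walk(a, d)
}

oracle_classify <- function(a, b) {
  paths <- oracle_pathways(a, b)
  ok <- !vapply(paths, `[[`, logical(1), "hit_stop")
  if (!any(ok)) ok <- rep(TRUE, length(paths))
  syn <- mean(vapply(paths[ok], `[[`, numeric(1), "syn"))
  nonsyn <- mean(vapply(paths[ok], `[[`, numeric(1), "nonsyn"))
  c(syn = syn, nonsyn = nonsyn)
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# write a small aligned FASTA and return its path
write_fixture_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}
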