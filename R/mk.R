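STOP_AA <- "*"

codon_ok <- function(codon) {
  nchar(codon) == 3L && !grepl("[^ACGT]", codon)
}

translate_codon <- function(codon, code = Biostrings::GENETIC_CODE) {
  unname(code[[codon]])
}

# all 3! = 6 orderings of up to three positions, precomputed
.perms <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Classify a codon change into synonymous and nonsynonymous steps
#'
#' For two sense codons differing at `k` positions (`k <= 3`), enumerates
#' all `k!` single-step mutational pathways between them, discards pathways
#' that pass through a stop codon (unless every pathway does, in which case
#' all are kept), labels each step synonymous or nonsynonymous under the
#' genetic code, and averages the per-step labels over the retained
#' pathways.  The result may be fractional; `syn + nonsyn = k` always.
#' This is the pathway-counting convention of Nei-Gojobori style methods.
#'
#' @param codon_a,codon_b Upper-case sense codons over `ACGT`.
#' @param code Genetic code table (named character vector codon -> amino
#'   acid, stop = `"*"`); defaults to the standard nuclear code.
#' @return Named numeric vector `c(syn = ..., nonsyn = ...)`.
#' @examples
#' classify_codon_change("TTA", "CTA")  # Leu -> Leu: synonymous
#' classify_codon_change("ATG", "ATA")  # Met -> Ile: nonsynonymous
#' @export
classify_codon_change <- function(codon_a, codon_b,
                                  code = Biostrings::GENETIC_CODE) {
  if (!codon_ok(codon_a) || !codon_ok(codon_b)) {
    stop("ambiguity error: codons must be 3-mers over ACGT (got '",
         codon_a, "', '", codon_b, "')", call. = FALSE)
  }
  if (translate_codon(codon_a, code) == STOP_AA ||
      translate_codon(codon_b, code) == STOP_AA) {
    stop("stop-codon error: '", codon_a, "' / '", codon_b,
         "' includes a stop codon", call. = FALSE)
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  d <- which(a != b)
  k <- length(d)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))

  paths <- .perms[[as.character(k)]]
  syn_per <- numeric(length(paths))
  valid <- logical(length(paths))
  for (p in seq_along(paths)) {
    cur <- a
    syn <- 0
    ok <- TRUE
    for (pos in d[paths[[p]]]) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa_cur <- translate_codon(paste(cur, collapse = ""), code)
      aa_nxt <- translate_codon(paste(nxt, collapse = ""), code)
      if (aa_nxt == STOP_AA) ok <- FALSE   # final codon is never a stop
      if (aa_cur == aa_nxt) syn <- syn + 1
      cur <- nxt
    }
    syn_per[p] <- syn
    valid[p] <- ok
  }
  keep <- if (any(valid)) valid else rep(TRUE, length(paths))
  syn <- mean(syn_per[keep])
  c(syn = syn, nonsyn = k - syn)
}

#' Construct an ingroup/outgroup codon panel
#'
#' @param ingroup Named character vector (or `DNAStringSet`) of `m >= 2`
#'   aligned coding sequences in a shared frame; length must be a multiple
#'   of 3.
#' @param outgroup A single aligned coding sequence of the same length.
#' @return A `divscan_panel` list with `ingroup`, `outgroup`, `m` and
#'   `n_codons`.
#' @export
codon_panel <- function(ingroup, outgroup) {
  ingroup <- toupper(as.character(ingroup))
  outgroup <- toupper(as.character(outgroup))
  if (length(outgroup) != 1L) stop("outgroup must be a single sequence",
                                   call. = FALSE)
  if (length(ingroup) < 2L) stop("need at least 2 ingroup sequences",
                                 call. = FALSE)
  lens <- unique(c(nchar(ingroup), nchar(outgroup)))
  if (length(lens) != 1L) {
    stop("frame error: panel sequences have unequal lengths", call. = FALSE)
  }
  if (lens %% 3L != 0L) {
    stop("frame error: sequence length ", lens, " is not a multiple of 3",
         call. = FALSE)
  }
  if (is.null(names(ingroup))) {
    names(ingroup) <- sprintf("strain_%02d", seq_along(ingroup))
  }
  structure(list(ingroup = ingroup, outgroup = outgroup,
                 m = length(ingroup), n_codons = lens %/% 3L),
            class = "divscan_panel")
}

#' Construct a McDonald-Kreitman 2x2 table
#'
#' @param Dn,Ds Nonsynonymous and synonymous fixed differences.
#' @param Pn,Ps Nonsynonymous and synonymous polymorphisms.
#' @return A `divscan_mktable` with the four counts (fractional values from
#'   pathway averaging are allowed) and the neutrality index
#'   `NI = (Pn/Ps)/(Dn/Ds)` where defined (`NA` otherwise).
#' @export
mk_table <- function(Dn = 0, Ds = 0, Pn = 0, Ps = 0) {
  stopifnot(Dn >= 0, Ds >= 0, Pn >= 0, Ps >= 0)
  ni <- if (Ps > 0 && Dn > 0 && Ds > 0) (Pn / Ps) / (Dn / Ds) else NA_real_
  structure(list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps, NI = ni),
            class = "divscan_mktable")
}

#' @export
print.divscan_mktable <- function(x, ...) {
  cat("McDonald-Kreitman table\n")
  m <- matrix(c(x$Dn, x$Pn, x$Ds, x$Ps), 2, 2,
              dimnames = list(c("fixed", "polymorphic"),
                              c("nonsynonymous", "synonymous")))
  print(m)
  if (!is.na(x$NI)) cat(sprintf("neutrality index NI = %.4f\n", x$NI))
  invisible(x)
}

as_mk_matrix <- function(table) {
  if (inherits(table, "divscan_mktable")) {
    matrix(c(table$Dn, table$Pn, table$Ds, table$Ps), 2, 2,
           dimnames = list(c("fixed", "polymorphic"),
                           c("nonsynonymous", "synonymous")))
  } else if (inherits(table, "divscan_regiontable")) {
    table$counts
  } else if (is.matrix(table) && all(dim(table) == c(2L, 2L))) {
    table
  } else {
    stop("expected an mk_table, region table or 2x2 matrix", call. = FALSE)
  }
}

#' Count MK cells from a codon panel
#'
#' Walks codon columns of an aligned ingroup panel plus one outgroup
#' sequence.  Per codon, ingroup sequences with a gap or ambiguous base in
#' that codon are dropped and alleles at frequency at or below
#' `maf_threshold` are excluded; codons with a gap/ambiguity in the
#' outgroup, or with no ingroup allele surviving the filter, are skipped
#' with a warning.  A codon is polymorphic when 2 or more ingroup alleles
#' remain (each minor allele is classified against the ingroup consensus,
#' the most frequent allele, ties broken alphabetically), and a fixed
#' difference when the post-filter ingroup is monomorphic and differs from
#' the outgroup (classified against the outgroup codon).  A codon both
#' polymorphic and divergent counts as polymorphic only.
#'
#' @param panel A `divscan_panel` from [codon_panel()].
#' @param maf_threshold Minor-allele frequency cutoff: alleles at frequency
#'   `<= maf_threshold` are dropped before classification (default 0, i.e.
#'   all observed alleles count; 0.01 reproduces a "rare below 1 percent"
#'   filter).
#' @param code Genetic code table.
#' @return A `divscan_mktable` with pathway-averaged (possibly fractional)
#'   `Dn`, `Ds`, `Pn`, `Ps`.
#' @export
count_mk <- function(panel, maf_threshold = 0,
                     code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(panel, "divscan_panel"))
  Dn <- Ds <- Pn <- Ps <- 0
  skipped <- 0L
  for (ci in seq_len(panel$n_codons)) {
    from <- 3L * ci - 2L
    cod_in <- substr(panel$ingroup, from, from + 2L)
    cod_out <- substr(panel$outgroup, from, from + 2L)
    cod_in <- cod_in[!grepl("[^ACGT]", cod_in)]
    if (grepl("[^ACGT]", cod_out) || length(cod_in) == 0L) {
      skipped <- skipped + 1L
      next
    }
    tab <- sort(table(cod_in), decreasing = TRUE)
    freq <- tab / sum(tab)
    tab <- tab[freq > maf_threshold]
    if (length(tab) == 0L) {
      skipped <- skipped + 1L
      next
    }
    # consensus = most frequent allele; deterministic alphabetic tie-break
    alleles <- names(tab)[order(-as.vector(tab), names(tab))]
    stops <- vapply(alleles, function(cd) translate_codon(cd, code) == STOP_AA,
                    logical(1))
    if (stops[1]) {
      skipped <- skipped + 1L
      next
    }
    consensus <- alleles[1]
    if (length(alleles) >= 2L) {
      for (al in alleles[-1]) {
        if (translate_codon(al, code) == STOP_AA) {
          skipped <- skipped + 1L
          next
        }
        cls <- classify_codon_change(consensus, al, code)
        Ps <- Ps + cls[["syn"]]
        Pn <- Pn + cls[["nonsyn"]]
      }
    } else if (consensus != cod_out) {
      if (translate_codon(cod_out, code) == STOP_AA) {
        skipped <- skipped + 1L
        next
      }
      cls <- classify_codon_change(consensus, cod_out, code)
      Ds <- Ds + cls[["syn"]]
      Dn <- Dn + cls[["nonsyn"]]
    }
  }
  if (skipped > 0L) {
    warning(skipped, " codon column(s) skipped (gaps, ambiguity, stop ",
            "codons, or empty after frequency filter)")
  }
  mk_table(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps)
}

#' Contingency test on an MK (or region) 2x2 table
#'
#' Tests whether the ratio of counts in the first column to the second
#' differs between fixed differences and polymorphisms.  `chi2` is the
#' Pearson chi-square without continuity correction on one degree of
#' freedom (fractional, pathway-averaged counts are permitted); `gtest` is
#' the likelihood-ratio G statistic, also on 1 df; `fisher` is the exact
#' test on counts rounded to the nearest integer (a warning is issued when
#' rounding changes the table).
#'
#' @param table A `divscan_mktable`, a region table from
#'   [count_region_mk()], or a plain 2x2 matrix (rows = fixed/polymorphic).
#' @param method `"chi2"` (default), `"fisher"` or `"gtest"`.
#' @return A `divscan_mkresult` with `statistic`, `p_value`, `method` and
#'   the input `table`.
#' @examples
#' mk_significance(mk_table(Dn = 10, Ds = 0, Pn = 0, Ps = 10))  # chi2 = 20
#' @export
mk_significance <- function(table, method = c("chi2", "fisher", "gtest")) {
  method <- match.arg(method)
  m <- as_mk_matrix(table)
  if (any(m < 0) || any(!is.finite(m))) {
    stop("table entries must be finite and non-negative", call. = FALSE)
  }
  rs <- rowSums(m)
  cs <- colSums(m)
  if (all(m == 0)) {
    stop("degenerate-table error: all counts are zero", call. = FALSE)
  }
  if (method %in% c("chi2", "gtest") && (any(rs == 0) || any(cs == 0))) {
    stop("degenerate-table error: a zero marginal makes the ", method,
         " statistic undefined; use method = 'fisher'", call. = FALSE)
  }
  if (method == "chi2") {
    E <- outer(rs, cs) / sum(m)
    stat <- sum((m - E)^2 / E)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else if (method == "gtest") {
    E <- outer(rs, cs) / sum(m)
    nz <- m > 0
    stat <- 2 * sum(m[nz] * log(m[nz] / E[nz]))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    mr <- round(m)
    if (any(mr != m)) {
      warning("fractional counts rounded to integers for Fisher's exact test")
    }
    ft <- stats::fisher.test(mr)
    stat <- NA_real_
    p <- ft$p.value
  }
  structure(list(statistic = unname(stat), p_value = unname(p),
                 method = method, table = table),
            class = "divscan_mkresult")
}

#' @export
print.divscan_mkresult <- function(x, ...) {
  cat(sprintf("MK contingency test (%s): statistic = %s, p = %.4g\n",
              x$method,
              if (is.na(x$statistic)) "NA" else sprintf("%.4f", x$statistic),
              x$p_value))
  invisible(x)
}

validate_regions <- function(regions, L) {
  need <- c("label", "start", "end")
  if (!all(need %in% names(regions))) {
    stop("annotation error: regions need columns label, start, end",
         call. = FALSE)
  }
  if (any(regions$start < 1L) || any(regions$end > L) ||
      any(regions$start > regions$end)) {
    stop("annotation error: region intervals outside 1..", L, call. = FALSE)
  }
  o <- order(regions$start)
  r <- regions[o, , drop = FALSE]
  if (nrow(r) > 1L && any(r$start[-1] <= r$end[-nrow(r)])) {
    stop("annotation error: overlapping region intervals", call. = FALSE)
  }
  bad <- setdiff(unique(regions$label), c("upstream", "intron", "cds"))
  if (length(bad)) {
    stop("annotation error: unknown region label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(regions)
}

#' Region-based MK counts: upstream noncoding vs silent sites
#'
#' The noncoding variant of the MK contrast: counts fixed differences and
#' polymorphisms at columns annotated `upstream`, and compares them with
#' the silent class, defined as synonymous coding changes (from the `cds`
#' regions, counted through the codon machinery of [count_mk()]) plus all
#' changes at `intron` columns.  Fixed vs polymorphic is defined exactly as
#' in [count_mk()]: a site both polymorphic within the ingroup and
#' different from the outgroup counts as polymorphic only.
#'
#' @param aln A `divscan_aln` holding the ingroup panel and the outgroup
#'   over a common alignment.
#' @param outgroup_id Identifier of the outgroup sequence; all other
#'   records form the ingroup.
#' @param regions Data frame with columns `label` (one of `upstream`,
#'   `intron`, `cds`), `start`, `end` (1-based closed alignment columns);
#'   intervals must not overlap.  Concatenated `cds` intervals (in
#'   coordinate order) must give a length that is a multiple of 3 and are
#'   read in the forward frame.
#' @param maf_threshold Allele-frequency filter as in [count_mk()].
#' @param code Genetic code table.
#' @return A `divscan_regiontable`: list with `counts` (2x2 matrix, rows
#'   fixed/polymorphic, columns upstream/silent) and the component tallies.
#' @export
count_region_mk <- function(aln, outgroup_id, regions, maf_threshold = 0,
                            code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(aln, "divscan_aln"))
  if (!outgroup_id %in% aln$ids) {
    stop("lookup error: no sequence '", outgroup_id, "'", call. = FALSE)
  }
  validate_regions(regions, aln$L)
  ingroup_ids <- setdiff(aln$ids, outgroup_id)
  if (length(ingroup_ids) < 2L) {
    stop("need at least 2 ingroup sequences besides the outgroup",
         call. = FALSE)
  }
  mat <- do.call(rbind, lapply(ingroup_ids,
                               function(id) aln_chars(aln, id)))
  out <- aln_chars(aln, outgroup_id)

  # site-level counting for noncoding columns
  count_sites <- function(cols) {
    fixed <- poly <- 0L
    for (cc in cols) {
      bases <- mat[, cc]
      bases <- bases[!bases %in% c("-", "N")]
      if (length(bases) == 0L || out[cc] %in% c("-", "N")) next
      tab <- table(bases)
      tab <- tab[tab / sum(tab) > maf_threshold]
      if (length(tab) == 0L) next
      if (length(tab) >= 2L) {
        poly <- poly + length(tab) - 1L   # one change per minor allele
      } else if (names(tab)[1] != out[cc]) {
        fixed <- fixed + 1L
      }
    }
    c(fixed = fixed, poly = poly)
  }

  cols_of <- function(lab) {
    r <- regions[regions$label == lab, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    unlist(lapply(seq_len(nrow(r)), function(i) r$start[i]:r$end[i]),
           use.names = FALSE)
  }

  up <- count_sites(cols_of("upstream"))
  intr <- count_sites(cols_of("intron"))

  syn_fixed <- syn_poly <- 0
  cds_cols <- cols_of("cds")
  if (length(cds_cols)) {
    if (length(cds_cols) %% 3L != 0L) {
      stop("frame error: cds regions total ", length(cds_cols),
           " columns, not a multiple of 3", call. = FALSE)
    }
    collapse <- function(ch) paste(ch[cds_cols], collapse = "")
    cds_in <- vapply(ingroup_ids,
                     function(id) collapse(aln_chars(aln, id)), character(1))
    panel <- codon_panel(cds_in, collapse(out))
    cm <- suppressWarnings(count_mk(panel, maf_threshold, code))
    syn_fixed <- cm$Ds
    syn_poly <- cm$Ps
  }

  counts <- matrix(c(up[["fixed"]], up[["poly"]],
                     intr[["fixed"]] + syn_fixed,
                     intr[["poly"]] + syn_poly),
                   2, 2,
                   dimnames = list(c("fixed", "polymorphic"),
                                   c("upstream", "silent")))
  structure(list(counts = counts,
                 upstream = up,
                 intron = intr,
                 synonymous = c(fixed = syn_fixed, poly = syn_poly)),
            class = "divscan_regiontable")
}

#' @export
print.divscan_regiontable <- function(x, ...) {
  cat("Region-based MK table (upstream vs silent)\n")
  print(x$counts)
  invisible(x)
}
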