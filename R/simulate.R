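BASES <- c("A", "C", "G", "T")

#' Specification of a synthetic pairwise alignment
#'
#' Describes the statistical model the hotspot scan assumes: a uniform
#' background of substitutions over the alignment plus optional windows of
#' elevated substitution density and indel (gap) runs.
#'
#' @param L Alignment length in columns.
#' @param n_background Background substitutions, placed uniformly without
#'   replacement outside the windows and indel runs.
#' @param windows Data frame with columns `start`, `end`, `n_events`:
#'   non-overlapping intervals each receiving exactly `n_events`
#'   substitutions at distinct columns.  `NULL` for a pure null alignment.
#' @param indel_runs Data frame with columns `start`, `length`: runs of gap
#'   columns placed in the second sequence.  Must not overlap windows.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `divscan_hotspotspec` list.
#' @export
hotspot_spec <- function(L, n_background = 0L, windows = NULL,
                         indel_runs = NULL, seed = NULL) {
  L <- as.integer(L)
  stopifnot(L >= 1L, n_background >= 0L)
  win_cols <- integer(0)
  if (!is.null(windows) && nrow(windows)) {
    stopifnot(all(c("start", "end", "n_events") %in% names(windows)))
    if (any(windows$start < 1L) || any(windows$end > L) ||
        any(windows$start > windows$end)) {
      stop("spec error: windows outside 1..L", call. = FALSE)
    }
    w <- windows[order(windows$start), , drop = FALSE]
    if (nrow(w) > 1L && any(w$start[-1] <= w$end[-nrow(w)])) {
      stop("spec error: overlapping windows", call. = FALSE)
    }
    if (any(windows$n_events > windows$end - windows$start + 1L)) {
      stop("spec error: more events than columns in a window", call. = FALSE)
    }
    win_cols <- unlist(mapply(seq, windows$start, windows$end,
                              SIMPLIFY = FALSE))
  }
  indel_cols <- integer(0)
  if (!is.null(indel_runs) && nrow(indel_runs)) {
    stopifnot(all(c("start", "length") %in% names(indel_runs)))
    indel_cols <- unlist(mapply(function(s, l) seq(s, s + l - 1L),
                                indel_runs$start, indel_runs$length,
                                SIMPLIFY = FALSE))
    if (any(indel_cols < 1L) || any(indel_cols > L) ||
        anyDuplicated(indel_cols)) {
      stop("spec error: indel runs outside 1..L or overlapping",
           call. = FALSE)
    }
    if (length(intersect(indel_cols, win_cols))) {
      stop("spec error: indel runs overlap event windows", call. = FALSE)
    }
  }
  total_events <- n_background +
    if (is.null(windows)) 0L else sum(windows$n_events)
  if (total_events > L - length(indel_cols)) {
    stop("spec error: more events than available columns", call. = FALSE)
  }
  bg_pool <- setdiff(seq_len(L), c(win_cols, indel_cols))
  if (n_background > length(bg_pool)) {
    stop("spec error: not enough columns outside windows for the background",
         call. = FALSE)
  }
  structure(list(L = L, n_background = as.integer(n_background),
                 windows = windows, indel_runs = indel_runs, seed = seed),
            class = "divscan_hotspotspec")
}

# sample() without its surprising scalar-x behaviour
sample_exact <- function(pool, k) {
  if (k == 0L) return(integer(0))
  pool[sample.int(length(pool), k)]
}

#' Simulate a two-species pairwise alignment with planted events
#'
#' Builds a random ancestral sequence, copies it, and plants substitutions
#' (background columns drawn uniformly without replacement outside the
#' windows; each window receiving exactly its event count at distinct
#' columns) by mutating the second sequence to a uniformly chosen different
#' base.  Indel runs become gap columns in the second sequence.  Output is
#' byte-reproducible under a fixed seed.
#'
#' @param spec A `divscan_hotspotspec` from [hotspot_spec()].
#' @param ids Identifiers for the two sequences.
#' @return List with `alignment` (a `divscan_aln`) and `truth`: the planted
#'   `event_columns` (sorted), a per-event `in_window` flag, the window
#'   table and the indel table.
#' @export
simulate_pair <- function(spec, ids = c("species_a", "species_b")) {
  stopifnot(inherits(spec, "divscan_hotspotspec"), length(ids) == 2L)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- spec$L
  anc <- sample(BASES, L, replace = TRUE)

  indel_cols <- integer(0)
  if (!is.null(spec$indel_runs) && nrow(spec$indel_runs)) {
    indel_cols <- unlist(mapply(function(s, l) seq(s, s + l - 1L),
                                spec$indel_runs$start,
                                spec$indel_runs$length, SIMPLIFY = FALSE))
  }
  win_cols <- integer(0)
  win_events <- integer(0)
  if (!is.null(spec$windows) && nrow(spec$windows)) {
    win_cols <- unlist(mapply(seq, spec$windows$start, spec$windows$end,
                              SIMPLIFY = FALSE))
    win_events <- unlist(lapply(seq_len(nrow(spec$windows)), function(i) {
      sample_exact(spec$windows$start[i]:spec$windows$end[i],
                   spec$windows$n_events[i])
    }))
  }
  bg_pool <- setdiff(seq_len(L), c(win_cols, indel_cols))
  bg_events <- sample_exact(bg_pool, spec$n_background)

  derived <- anc
  for (cc in c(bg_events, win_events)) {
    derived[cc] <- sample(setdiff(BASES, anc[cc]), 1L)
  }
  derived[indel_cols] <- "-"

  cols <- sort(c(bg_events, win_events))
  seqs <- c(paste(anc, collapse = ""), paste(derived, collapse = ""))
  names(seqs) <- ids
  list(alignment = new_alignment(seqs),
       truth = list(event_columns = cols,
                    in_window = cols %in% win_cols,
                    windows = spec$windows,
                    indel_runs = spec$indel_runs))
}

#' Specification of a synthetic MK codon panel
#'
#' One planted event per codon, so the generator's bookkeeping is exact:
#' [count_mk()] on the simulated panel recovers the planted table without
#' pathway averaging.
#'
#' @param n_codons Codons per sequence.
#' @param m_strains Ingroup panel size (`>= 2`).
#' @param Pn,Ps Planted nonsynonymous/synonymous polymorphisms.
#' @param Dn,Ds Planted nonsynonymous/synonymous fixed differences.
#' @param poly_freq Derived-allele frequency for polymorphic sites (the
#'   derived count is clamped to `1..m_strains - 1` so sites stay
#'   polymorphic); default 0.5.
#' @param seed Integer seed.
#' @return A `divscan_mkpanelspec` list.
#' @export
mk_panel_spec <- function(n_codons, m_strains, Pn = 0L, Ps = 0L,
                          Dn = 0L, Ds = 0L, poly_freq = 0.5, seed = NULL) {
  stopifnot(m_strains >= 2L, n_codons >= 1L,
            Pn >= 0L, Ps >= 0L, Dn >= 0L, Ds >= 0L,
            poly_freq > 0, poly_freq < 1)
  if (Pn + Ps + Dn + Ds > n_codons) {
    stop("spec error: more planted events (", Pn + Ps + Dn + Ds,
         ") than codons (", n_codons, ")", call. = FALSE)
  }
  structure(list(n_codons = as.integer(n_codons),
                 m_strains = as.integer(m_strains),
                 Pn = as.integer(Pn), Ps = as.integer(Ps),
                 Dn = as.integer(Dn), Ds = as.integer(Ds),
                 poly_freq = poly_freq, seed = seed),
            class = "divscan_mkpanelspec")
}

# single-base codon moves between sense codons, labelled synonymous or not
codon_moves <- function(code = Biostrings::GENETIC_CODE) {
  sense <- names(code)[code != STOP_AA]
  moves <- list()
  for (cd in sense) {
    ch <- strsplit(cd, "")[[1]]
    for (pos in 1:3) {
      for (alt in setdiff(BASES, ch[pos])) {
        nw <- ch
        nw[pos] <- alt
        nwc <- paste(nw, collapse = "")
        if (code[[nwc]] == STOP_AA) next
        moves[[length(moves) + 1L]] <-
          data.frame(from = cd, to = nwc,
                     syn = code[[cd]] == code[[nwc]],
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, moves)
}

#' Simulate an ingroup/outgroup codon panel with planted MK counts
#'
#' Assigns each planted event to a distinct codon.  Synonymous events use a
#' code-verified synonymous single-base change between sense codons,
#' nonsynonymous events likewise; polymorphic events place the derived
#' codon in a random strain subset at the spec'd frequency, fixed
#' differences place it in the outgroup.  The returned truth equals the
#' planted table exactly.
#'
#' @param spec A `divscan_mkpanelspec` from [mk_panel_spec()].
#' @return List with `panel` (a `divscan_panel`) and `truth` (a
#'   `divscan_mktable`).
#' @export
simulate_mk_panel <- function(spec) {
  stopifnot(inherits(spec, "divscan_mkpanelspec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  moves <- codon_moves()
  syn_moves <- moves[moves$syn, , drop = FALSE]
  non_moves <- moves[!moves$syn, , drop = FALSE]
  m <- spec$m_strains
  nc <- spec$n_codons

  sense <- unique(moves$from)
  anc <- sample(sense, nc, replace = TRUE)
  panel <- matrix(rep(anc, each = m), nrow = m)   # strains x codons
  outgroup <- anc

  e_total <- spec$Pn + spec$Ps + spec$Dn + spec$Ds
  slots <- sample_exact(seq_len(nc), e_total)
  kinds <- rep(c("Pn", "Ps", "Dn", "Ds"),
               times = c(spec$Pn, spec$Ps, spec$Dn, spec$Ds))
  k_derived <- max(1L, min(m - 1L, round(spec$poly_freq * m)))

  for (e in seq_along(slots)) {
    ci <- slots[e]
    pool <- if (kinds[e] %in% c("Ps", "Ds")) syn_moves else non_moves
    mv <- pool[sample.int(nrow(pool), 1L), ]
    panel[, ci] <- mv$from
    outgroup[ci] <- mv$from
    if (kinds[e] %in% c("Pn", "Ps")) {
      carriers <- sample_exact(seq_len(m), k_derived)
      panel[carriers, ci] <- mv$to
    } else {
      outgroup[ci] <- mv$to
    }
  }

  ingroup <- apply(panel, 1L, paste, collapse = "")
  names(ingroup) <- sprintf("strain_%02d", seq_len(m))
  list(panel = codon_panel(ingroup, paste(outgroup, collapse = "")),
       truth = mk_table(Dn = spec$Dn, Ds = spec$Ds,
                        Pn = spec$Pn, Ps = spec$Ps))
}
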