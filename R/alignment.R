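#' Read an aligned FASTA file
#'
#' Reads a multiple-sequence alignment in aligned FASTA format and validates
#' it: all records must have identical length, identifiers must be unique,
#' and the alphabet is restricted to `A`, `C`, `G`, `T`, `N`, `U` and the
#' gap character `-` (case-insensitive; `U` is normalised to `T`).
#'
#' @param path Path to an aligned FASTA file.
#' @param format Input format; only `"aligned-fasta"` is supported.
#' @return A `divscan_aln` object: a list with elements `ids` (character),
#'   `seq` (named character vector of upper-case aligned sequences) and `L`
#'   (alignment length in columns).
#' @examples
#' tmp <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), tmp)
#' aln <- read_alignment(tmp)
#' aln$L
#' @export
read_alignment <- function(path, format = "aligned-fasta") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) {
    stop("format error: no FASTA records in ", path, call. = FALSE)
  }
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", names(recs))
  new_alignment(as.character(recs), ids)
}

#' Construct an alignment from sequences in memory
#'
#' @param seqs Character vector of aligned sequences (may contain gaps `-`).
#' @param ids Sequence identifiers; defaults to names of `seqs`.
#' @return A `divscan_aln` object (see [read_alignment()]).
#' @export
new_alignment <- function(seqs, ids = names(seqs)) {
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every alignment record needs a non-empty identifier", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(seqs) < 2L) {
    stop("an alignment needs at least 2 records", call. = FALSE)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment-shape error: records have unequal lengths (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  }
  if (lens[1] < 1L) {
    stop("alignment-shape error: zero-length alignment", call. = FALSE)
  }
  seqs <- toupper(seqs)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- regexpr("[^ACGTN-]", seqs)
  if (any(bad > 0L)) {
    k <- which(bad > 0L)[1]
    stop("alphabet error: record '", ids[k], "' has invalid character '",
         substr(seqs[k], bad[k], bad[k]), "' at column ", bad[k],
         call. = FALSE)
  }
  names(seqs) <- ids
  structure(list(ids = ids, seq = seqs, L = unname(lens[1])),
            class = "divscan_aln")
}

#' Write an alignment to aligned FASTA
#'
#' @param aln A `divscan_aln` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "divscan_aln"))
  x <- Biostrings::BStringSet(aln$seq)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' @export
print.divscan_aln <- function(x, ...) {
  cat(sprintf("Alignment: %d records x %d columns\n", length(x$ids), x$L))
  for (id in utils::head(x$ids, 6)) {
    s <- x$seq[[id]]
    cat(sprintf("  %-20s %s%s\n", id, substr(s, 1, 50),
                if (x$L > 50) "..." else ""))
  }
  if (length(x$ids) > 6) cat("  ...\n")
  invisible(x)
}

aln_chars <- function(aln, id) {
  if (!id %in% aln$ids) {
    stop("lookup error: no sequence '", id, "' in alignment", call. = FALSE)
  }
  strsplit(aln$seq[[id]], "", fixed = TRUE)[[1]]
}

#' Extract substitution and indel events from a pairwise comparison
#'
#' Compares two sequences of an alignment column by column.  A substitution
#' event is a column where both bases are non-gap (and, with
#' `mask_ambiguous = TRUE`, non-`N`) and differ.  A maximal run of gap
#' columns present in exactly one of the two sequences is an indel event;
#' with `include_indels = TRUE` each indel contributes one event position
#' anchored at its first column.  Columns gapped in both sequences
#' contribute nothing but still count towards the alignment length `L`.
#'
#' @param aln A `divscan_aln` object.
#' @param seq_a,seq_b Identifiers of the two sequences to compare.
#' @param include_indels Count each indel run as one event at its start
#'   column (default `FALSE`: substitutions only).
#' @param mask_ambiguous Exclude columns with `N` in either sequence from
#'   substitution events (default `TRUE`).
#' @return A `divscan_events` object: list with `L`, `n`, `positions`
#'   (strictly increasing event columns, 1-based), `events` (data frame
#'   with `column`, `end`, `ref`, `alt`, `kind`), `universe` (columns where
#'   both sequences are non-gap) and the two identifiers.
#' @examples
#' aln <- new_alignment(c(a = "ACGTAC", b = "AGGTAT"))
#' ev <- extract_events(aln, "a", "b")
#' ev$positions  # columns 2 and 6
#' @export
extract_events <- function(aln, seq_a, seq_b, include_indels = FALSE,
                           mask_ambiguous = TRUE) {
  stopifnot(inherits(aln, "divscan_aln"))
  if (identical(seq_a, seq_b)) {
    stop("degenerate-input error: seq_a and seq_b are the same sequence",
         call. = FALSE)
  }
  a <- aln_chars(aln, seq_a)
  b <- aln_chars(aln, seq_b)
  ga <- a == "-"
  gb <- b == "-"
  both_ungapped <- !ga & !gb

  is_sub <- both_ungapped & a != b
  if (mask_ambiguous) {
    is_sub <- is_sub & a != "N" & b != "N"
  }
  subs <- which(is_sub)
  ev <- data.frame(column = subs, end = subs, ref = a[subs], alt = b[subs],
                   kind = rep("substitution", length(subs)),
                   stringsAsFactors = FALSE)

  # maximal gap runs present in exactly one sequence
  indels <- data.frame(column = integer(0), end = integer(0),
                       ref = character(0), alt = character(0),
                       kind = character(0), stringsAsFactors = FALSE)
  gap_one <- xor(ga, gb)
  if (any(gap_one)) {
    # split runs of one-sided gaps by which sequence carries the gap, so a
    # gap in a abutting a gap in b yields two indel events
    code <- ifelse(ga & !gb, 1L, ifelse(gb & !ga, 2L, 0L))
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_in <- r$values != 0L
    if (any(run_in)) {
      st <- starts[run_in]
      en <- ends[run_in]
      gapped_in_a <- r$values[run_in] == 1L
      indels <- data.frame(
        column = st, end = en,
        ref = NA_character_, alt = NA_character_,
        kind = rep("indel", length(st)),
        stringsAsFactors = FALSE)
      # identifier of the gapless (base-carrying) sequence for each run
      indels$inserted_in <- ifelse(gapped_in_a, seq_b, seq_a)
    }
  }
  if (nrow(indels)) {
    ev$inserted_in <- rep(NA_character_, nrow(ev))
    ev <- rbind(ev, indels)
  }
  ev <- ev[order(ev$column), , drop = FALSE]
  rownames(ev) <- NULL

  counted <- if (include_indels) ev else ev[ev$kind == "substitution", ,
                                            drop = FALSE]
  positions <- sort(unique(counted$column))
  structure(list(
    L = aln$L,
    n = length(positions),
    positions = positions,
    events = ev,
    universe = which(both_ungapped),
    seq_a = seq_a, seq_b = seq_b,
    include_indels = include_indels
  ), class = "divscan_events")
}

#' Construct an event set from bare positions
#'
#' Convenience constructor used by simulations and tests: wraps ordered
#' event columns over an alignment of length `L` into the same object
#' [extract_events()] returns.
#'
#' @param positions Integer vector of event columns in `1..L`.
#' @param L Alignment length (columns).
#' @param universe Optional position universe (defaults to `1:L`).
#' @return A `divscan_events` object.
#' @export
event_set <- function(positions, L, universe = seq_len(L)) {
  positions <- sort(unique(as.integer(positions)))
  if (length(positions) && (positions[1] < 1L || positions[length(positions)] > L)) {
    stop("event positions must lie in 1..L", call. = FALSE)
  }
  structure(list(L = as.integer(L), n = length(positions),
                 positions = positions,
                 events = data.frame(column = positions, end = positions,
                                     ref = rep(NA_character_, length(positions)),
                                     alt = rep(NA_character_, length(positions)),
                                     kind = rep("substitution", length(positions)),
                                     stringsAsFactors = FALSE),
                 universe = as.integer(universe),
                 seq_a = NA_character_, seq_b = NA_character_,
                 include_indels = FALSE),
            class = "divscan_events")
}

#' @export
print.divscan_events <- function(x, ...) {
  cat(sprintf("Event set: n = %d events over L = %d columns (%s vs %s)\n",
              x$n, x$L,
              ifelse(is.na(x$seq_a), "?", x$seq_a),
              ifelse(is.na(x$seq_b), "?", x$seq_b)))
  nsub <- sum(x$events$kind == "substitution")
  nind <- sum(x$events$kind == "indel")
  cat(sprintf("  %d substitutions, %d indel runs (indels %scounted)\n",
              nsub, nind, if (isTRUE(x$include_indels)) "" else "not "))
  invisible(x)
}

#' Map alignment columns to ungapped reference coordinates
#'
#' Builds the column-to-offset table for one (reference) sequence of the
#' alignment.  Non-gap reference columns map to consecutive offsets starting
#' at `anchor_offset`; a negative anchor yields promoter-style coordinates
#' relative to a TSS.  Columns where the reference is gapped (insertions
#' relative to the reference) map to the preceding reference offset and are
#' flagged; leading gap columns map to `NA`.
#'
#' @param aln A `divscan_aln` object.
#' @param reference_id Identifier of the reference sequence.
#' @param anchor_offset Offset assigned to the first non-gap reference
#'   column (default 1).
#' @return A `divscan_coordmap`: list with `reference_id`, `anchor_offset`,
#'   `offset` (integer vector, one per alignment column) and `insertion`
#'   (logical vector).
#' @examples
#' aln <- new_alignment(c(ref = "AC-GT", other = "ACTGT"))
#' cm <- map_to_reference(aln, "ref", anchor_offset = -5)
#' cm$offset  # -5 -4 -4 -3 -2 ; column 3 is an insertion
#' @export
map_to_reference <- function(aln, reference_id, anchor_offset = 1L) {
  stopifnot(inherits(aln, "divscan_aln"))
  ref <- aln_chars(aln, reference_id)
  nongap <- ref != "-"
  if (!any(nongap)) {
    stop("degenerate-input error: reference '", reference_id,
         "' is all gaps", call. = FALSE)
  }
  offset <- rep(NA_integer_, aln$L)
  offset[nongap] <- anchor_offset + seq_len(sum(nongap)) - 1L
  # gap columns inherit the preceding reference offset (NA before the first)
  idx <- cummax(ifelse(nongap, seq_len(aln$L), 0L))
  has_prev <- !nongap & idx > 0L
  offset[has_prev] <- offset[idx[has_prev]]
  structure(list(reference_id = reference_id,
                 anchor_offset = as.integer(anchor_offset),
                 offset = offset,
                 insertion = !nongap),
            class = "divscan_coordmap")
}

#' Translate an alignment interval into reference coordinates
#'
#' @param cm A `divscan_coordmap` from [map_to_reference()].
#' @param start,end 1-based closed alignment-column interval.
#' @return Integer vector `c(start, end)` in reference coordinates (`NA`
#'   where the interval lies before the first reference base).
#' @export
map_interval <- function(cm, start, end) {
  stopifnot(inherits(cm, "divscan_coordmap"))
  L <- length(cm$offset)
  if (start < 1L || end > L || start > end) {
    stop("interval out of range 1..", L, call. = FALSE)
  }
  c(cm$offset[start], cm$offset[end])
}

#' Write events as TSV
#'
#' Columns: `column`, `end`, `ref`, `alt`, `kind` (1-based closed alignment
#' coordinates).
#'
#' @param events A `divscan_events` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(inherits(events, "divscan_events"))
  utils::write.table(events$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Data frame with 1-based closed `start`/`end` alignment
#'   columns and optionally `name` and `score` columns.
#' @param path Output path.
#' @param cm Optional `divscan_coordmap`: when given, coordinates are
#'   reported on the reference sequence named in the map.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, cm = NULL) {
  chrom <- if (is.null(cm)) "alignment" else cm$reference_id
  start <- intervals$start
  end <- intervals$end
  if (!is.null(cm)) {
    se <- t(vapply(seq_len(nrow(intervals)),
                   function(i) map_interval(cm, start[i], end[i]),
                   integer(2)))
    start <- se[, 1]
    end <- se[, 2]
  }
  bed <- data.frame(
    chrom = chrom,
    start = start - 1L,           # BED is 0-based half-open
    end = end,
    name = if ("name" %in% names(intervals)) intervals$name else ".",
    score = if ("score" %in% names(intervals)) intervals$score else 0)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
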