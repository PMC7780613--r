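#' Reconstruct the LU-level profile of a rearranged strain
#'
#' Statuses of every reference LU are derived from a `chromosome_state`
#' (or by replaying an event log): copy number, whether any copy is
#' inverted, deleted when no copy remains. Maximal runs of consecutive
#' deleted reference LUs are merged into deleted segments with reference
#' coordinates; segment spans are sums of the deleted LU lengths (loxPsym
#' sites excluded, as in all deleted-sequence accounting here).
#'
#' @param state a `chromosome_state` or `strain`.
#' @return an object of class `lu_profile`: list with `strain_id`,
#'   `status` (data.frame `lu_id`, `copies`, `inverted`, `deleted`) and
#'   `deleted_segments` (data.frame `first_lu`, `last_lu`, `start_bp`,
#'   `end_bp`, `span_bp`, `n_lus`).
#' @export
profile_from_state <- function(state) {
  id <- NA_character_
  if (inherits(state, "strain")) { id <- state$id; state <- state$state }
  chrom <- state$chrom
  lt <- lu_table(chrom)
  seg <- state$segments
  copies <- as.integer(table(factor(seg$lu, levels = lt$lu_id)))
  inverted <- as.logical(tapply(seg$orient == "-",
                                factor(seg$lu, levels = lt$lu_id), any))
  inverted[is.na(inverted)] <- FALSE
  status <- data.frame(lu_id = lt$lu_id, copies = copies,
                       inverted = inverted, deleted = copies == 0L,
                       stringsAsFactors = FALSE)
  structure(list(strain_id = id, status = status,
                 deleted_segments = .deleted_runs(status, lt)),
            class = "lu_profile")
}

.deleted_runs <- function(status, lt) {
  del <- status$deleted
  if (!any(del)) {
    return(data.frame(first_lu = character(), last_lu = character(),
                      start_bp = integer(), end_bp = integer(),
                      span_bp = integer(), n_lus = integer(),
                      stringsAsFactors = FALSE))
  }
  r <- rle(del)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(first_lu = lt$lu_id[starts[keep]],
             last_lu = lt$lu_id[ends[keep]],
             start_bp = lt$start[starts[keep]],
             end_bp = lt$end[ends[keep]],
             span_bp = vapply(keep, function(k) {
               sum(lt$length_bp[starts[k]:ends[k]])
             }, 0L),
             n_lus = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Profile a strain by replaying its event log against the reference
#'
#' @param chrom the reference `synthetic_chromosome`.
#' @param events event log (list of `type`/`i`/`j`).
#' @param strain_id optional id attached to the profile.
#' @return an `lu_profile`.
#' @export
profile_from_events <- function(chrom, events, strain_id = NA_character_) {
  state <- tryCatch(replay_events(chrom, events),
                    error = function(e) stop("event log is not replayable: ",
                                             conditionMessage(e)))
  p <- profile_from_state(state)
  p$strain_id <- strain_id
  p
}

#' @export
print.lu_profile <- function(x, ...) {
  cat(sprintf("lu_profile%s: %d/%d LUs deleted in %d segment(s)\n",
              if (is.na(x$strain_id)) "" else paste0(" [", x$strain_id, "]"),
              sum(x$status$deleted), nrow(x$status),
              nrow(x$deleted_segments)))
  invisible(x)
}

#' Emit the exact sequence of a rearranged strain's chromosome
#'
#' Concatenates the per-LU sequences of the current segments (reverse
#' complemented for inverted copies) with the palindromic loxPsym 34-mer at
#' every surviving site, mirroring an error-free assembled contig.
#'
#' @param state a `chromosome_state` whose reference carries sequence.
#' @return a character string.
#' @export
state_contig <- function(state) {
  chrom <- state$chrom
  if (is.null(chrom$lu_seqs)) stop("reference carries no sequence")
  pieces <- vapply(seq_len(nrow(state$segments)), function(k) {
    s <- chrom$lu_seqs[[state$segments$lu[k]]]
    if (state$segments$orient[k] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    s
  }, "")
  body <- if (length(pieces)) paste0(pieces, LOXPSYM_SEQ, collapse = "") else ""
  paste0(LOXPSYM_SEQ, body)
}

#' Reconstruct an LU profile from an error-free contig
#'
#' Greedy left-to-right tiling: after each loxPsym 34-mer the next stretch
#' must exactly match one reference LU sequence in forward or reverse
#' complement orientation. Copy numbers and orientations are accumulated;
#' any unmatched stretch is an error (simulated contigs are exact).
#'
#' @param chrom reference `synthetic_chromosome` with per-LU sequences.
#' @param contig character string (or `DNAString`).
#' @param strain_id optional id.
#' @return an `lu_profile`.
#' @export
profile_from_sequence <- function(chrom, contig, strain_id = NA_character_) {
  if (is.null(chrom$lu_seqs)) stop("reference carries no sequence")
  contig <- as.character(contig)
  fwd <- unlist(chrom$lu_seqs)
  rev <- vapply(fwd, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "")
  lens <- nchar(fwd)
  pos <- 1L
  n <- nchar(contig)
  if (substr(contig, 1L, LOXPSYM_BP) != LOXPSYM_SEQ) {
    stop("unrecognized sequence: contig does not start with a loxPsym site")
  }
  pos <- pos + LOXPSYM_BP
  seg_lu <- character(); seg_or <- character()
  while (pos <= n) {
    hit <- NA_integer_; orient <- NA_character_
    for (k in seq_along(fwd)) {
      end <- pos + lens[k] - 1L
      if (end > n) next
      chunk <- substr(contig, pos, end)
      if (chunk == fwd[k]) { hit <- k; orient <- "+"; break }
      if (chunk == rev[k]) { hit <- k; orient <- "-"; break }
    }
    if (is.na(hit)) stop("unrecognized sequence at position ", pos)
    seg_lu <- c(seg_lu, names(fwd)[hit]); seg_or <- c(seg_or, orient)
    pos <- pos + lens[hit]
    if (substr(contig, pos, pos + LOXPSYM_BP - 1L) != LOXPSYM_SEQ) {
      stop("missing loxPsym site at position ", pos)
    }
    pos <- pos + LOXPSYM_BP
  }
  pseudo <- new_state(chrom)
  pseudo$segments <- data.frame(lu = seg_lu, orient = seg_or,
                                stringsAsFactors = FALSE)
  pseudo$sites <- pseudo$sites[seq_len(length(seg_lu) + 1L), , drop = FALSE]
  p <- profile_from_state(pseudo)
  p$strain_id <- strain_id
  p
}

#' Design in-silico PCRtag primer pairs for each LU
#'
#' One convergent primer pair internal to each sufficiently long LU
#' (both primers within the unit, amplicon capped at `max_amplicon_bp`).
#' Units shorter than two primers are left untagged, mirroring real tag
#' tables in which some loxPsym units carry no PCRtag.
#'
#' @param chrom a `synthetic_chromosome` with sequence.
#' @param primer_bp primer length.
#' @param max_amplicon_bp maximal amplicon size.
#' @return data.frame `lu_id`, `fwd`, `rev` (primer sequences; `rev` is
#'   the reverse complement of the template top strand),
#'   `max_amplicon_bp`.
#' @export
make_pcrtags <- function(chrom, primer_bp = 20L, max_amplicon_bp = 500L) {
  if (is.null(chrom$lu_seqs)) stop("reference carries no sequence")
  rows <- lapply(chrom$lus$lu_id, function(id) {
    s <- chrom$lu_seqs[[id]]
    L <- nchar(s)
    if (L < 2L * primer_bp + 20L) return(NULL)
    amp <- min(max_amplicon_bp, L)
    fwd <- substr(s, 1L, primer_bp)
    rev_t <- substr(s, amp - primer_bp + 1L, amp)
    data.frame(lu_id = id, fwd = fwd,
               rev = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(rev_t))),
               max_amplicon_bp = amp, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' In-silico PCRtag screen of a strain
#'
#' Profile mode (a `chromosome_state`, `strain` or `lu_profile`): a tag is
#' positive iff its LU is present in at least one copy. Sequence mode (a
#' character contig): positive iff the forward primer and the reverse
#' primer's binding site occur convergently on one molecule within the
#' tag's amplicon limit (inversions keep amplicons internal to the LU, so
#' tags stay positive).
#'
#' @param x state/strain/profile, or a contig string.
#' @param tags data.frame from [make_pcrtags].
#' @param chrom reference; required in profile mode only to check tag ids.
#' @return data.frame `lu_id`, `positive`.
#' @export
insilico_pcrtag <- function(x, tags, chrom = NULL) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 200L) {
    # primers prime on double-stranded template: search both strands
    x_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
    amplifies <- function(strand, fwd, rev_rc, max_amp) {
      starts <- gregexpr(fwd, strand, fixed = TRUE)[[1L]]
      if (starts[1L] == -1L) return(FALSE)
      ends <- gregexpr(rev_rc, strand, fixed = TRUE)[[1L]]
      if (ends[1L] == -1L) return(FALSE)
      any(outer(as.integer(ends) + nchar(rev_rc) - 1L,
                as.integer(starts), "-") + 1L %in% seq_len(max_amp))
    }
    positive <- vapply(seq_len(nrow(tags)), function(k) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tags$rev[k])))
      amplifies(x, tags$fwd[k], rc, tags$max_amplicon_bp[k]) ||
        amplifies(x_rc, tags$fwd[k], rc, tags$max_amplicon_bp[k])
    }, FALSE)
    return(data.frame(lu_id = tags$lu_id, positive = positive,
                      stringsAsFactors = FALSE))
  }
  prof <- if (inherits(x, "lu_profile")) x else profile_from_state(x)
  known <- prof$status$lu_id
  if (!all(tags$lu_id %in% known)) {
    stop("tag references unknown LU: ",
         paste(setdiff(tags$lu_id, known), collapse = ", "))
  }
  copies <- setNames(prof$status$copies, prof$status$lu_id)
  data.frame(lu_id = tags$lu_id,
             positive = copies[tags$lu_id] >= 1L,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compaction statistics of one strain profile
#'
#' Deleted bp is the sum of reference lengths of the deleted LUs (loxPsym
#' sites excluded); deleted genes are counted from the reference gene
#' content of those LUs, including any gene that had been replaced by the
#' URA3 reporter (the reporter itself is a marker, not a gene).
#'
#' @param profile an `lu_profile`.
#' @param chrom the reference `synthetic_chromosome`.
#' @return list `n_lus_deleted`, `bp_deleted`, `n_genes_deleted`,
#'   `deleted_lus`.
#' @export
compaction_stats <- function(profile, chrom) {
  lt <- lu_table(chrom)
  del <- profile$status$lu_id[profile$status$deleted]
  list(n_lus_deleted = length(del),
       bp_deleted = sum(lt$length_bp[lt$lu_id %in% del]),
       n_genes_deleted = sum(chrom$genes$lu_id %in% del),
       deleted_lus = del)
}

#' Write strain profiles as TSV
#' @param profiles list of `lu_profile`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    cbind(strain = p$strain_id, p$status)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
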