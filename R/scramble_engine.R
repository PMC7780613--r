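#' Initial chromosome state of an unrearranged strain
#'
#' A `chromosome_state` is the current linear structure of a (possibly
#' rearranged) arm: an ordered list of signed segments, each referring to a
#' reference LU, separated and flanked by the surviving loxPsym sites.
#' `length(sites) == length(segments) + 1` always holds.
#'
#' @param chrom a `synthetic_chromosome` (the reference the state resolves
#'   against; kept by reference inside the state).
#' @param episomes character vector of episome names present (e.g.
#'   `"eArray"`).
#' @return an object of class `chromosome_state`.
#' @export
new_state <- function(chrom, episomes = character()) {
  n <- nrow(chrom$lus)
  structure(list(
    chrom = chrom,
    segments = data.frame(lu = chrom$lus$lu_id,
                          orient = rep("+", n), stringsAsFactors = FALSE),
    sites = data.frame(id = paste0("s", 0:n), origin = 0:n,
                       stringsAsFactors = FALSE),
    episomes = episomes,
    events = list()), class = "chromosome_state")
}

#' @export
print.chromosome_state <- function(x, ...) {
  cat(sprintf("chromosome_state: %d segments, %d sites, %d events%s\n",
              nrow(x$segments), nrow(x$sites), length(x$events),
              if (length(x$episomes)) paste0(" [", paste(x$episomes, collapse = ","), "]")
              else ""))
  invisible(x)
}

.seg_lengths <- function(state) {
  len <- setNames(state$chrom$lus$length_bp, state$chrom$lus$lu_id)
  unname(len[state$segments$lu])
}

#' Current linear coordinates of the surviving loxPsym sites
#' @param state a `chromosome_state`.
#' @return numeric vector of site start positions on the current molecule.
#' @export
state_site_positions <- function(state) {
  lens <- .seg_lengths(state)
  cumsum(c(0, lens + state$chrom$loxpsym_bp))
}

#' Reference-origin coordinates of the surviving sites
#'
#' Each surviving site is mapped back to the reference position of the
#' original site it derives from (the left parent, for hybrid junction
#' sites). Used by the Hi-C lookup and CID-boost weight models.
#' @param state a `chromosome_state`.
#' @return numeric vector of reference positions.
#' @export
reference_site_positions <- function(state) {
  st <- site_table(state$chrom)
  st$position[state$sites$origin + 1L]
}

#' Total synthetic bp carried by a state (LU lengths, sites excluded)
#' @param state a `chromosome_state`.
#' @return bp.
#' @export
state_bp <- function(state) sum(.seg_lengths(state))

#' Create a Cre recombination event
#' @param type `"deletion"`, `"inversion"` or `"duplication"`.
#' @param i,j 1-based indices into the current site list, `i < j`.
#' @return a `recombination_event` list.
#' @export
recombination_event <- function(type = c("deletion", "inversion", "duplication"),
                                i, j) {
  type <- match.arg(type)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("degenerate pair: i == j")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  structure(list(type = type, i = i, j = j), class = "recombination_event")
}

#' Apply one Cre recombination event to a chromosome state
#'
#' Recombination between surviving sites `i < j` acts on the segments
#' strictly between them. Deletion excises those segments together with the
#' interior sites, leaving a single hybrid site at the junction (the
#' excised circle is lost: it carries no centromere). Inversion reverses
#' the segment order and flips orientations, retaining both sites.
#' Duplication tandem-duplicates the block with one extra site at the
#' internal junction.
#'
#' @param state a `chromosome_state`.
#' @param event a `recombination_event` (or list with `type`, `i`, `j`).
#' @return the new `chromosome_state`, with the event (annotated with the
#'   affected LU refs) appended to its log.
#' @export
apply_event <- function(state, event) {
  ns <- nrow(state$sites)
  i <- event$i; j <- event$j
  if (i == j) stop("degenerate pair: i == j")
  if (i < 1L || j > ns || i > j) stop("site indices out of range")
  block <- seq.int(i, j - 1L)  # segment rows between sites i and j
  segs <- state$segments
  sites <- state$sites
  ev <- list(type = event$type, i = i, j = j,
             lus = segs$lu[block], order = length(state$events) + 1L)

  if (event$type == "deletion") {
    segs <- segs[-block, , drop = FALSE]
    hybrid <- data.frame(id = paste0(sites$id[i], "*"),
                         origin = sites$origin[i], stringsAsFactors = FALSE)
    sites <- rbind(sites[seq_len(i - 1L), , drop = FALSE], hybrid,
                   sites[seq.int(j + 1L, ns)[seq_len(ns - j)], , drop = FALSE])
  } else if (event$type == "inversion") {
    segs[block, ] <- data.frame(lu = rev(segs$lu[block]),
                                orient = ifelse(rev(segs$orient[block]) == "+",
                                                "-", "+"))
    interior <- seq.int(i + 1L, j - 1L)[seq_len(max(0L, j - i - 1L))]
    if (length(interior)) sites[interior, ] <- sites[rev(interior), ]
  } else if (event$type == "duplication") {
    segs <- rbind(segs[seq_len(j - 1L), , drop = FALSE],
                  segs[block, , drop = FALSE],
                  segs[seq.int(j, nrow(segs))[seq_len(nrow(segs) - j + 1L)], ,
                       drop = FALSE])
    interior <- sites[seq.int(i + 1L, j - 1L)[seq_len(max(0L, j - i - 1L))], ,
                      drop = FALSE]
    if (nrow(interior)) interior$id <- paste0(interior$id, "'")
    junction <- data.frame(id = paste0(sites$id[i], "^"),
                           origin = sites$origin[i], stringsAsFactors = FALSE)
    sites <- rbind(sites[seq_len(j - 1L), , drop = FALSE], junction, interior,
                   sites[seq.int(j, ns), , drop = FALSE])
  } else stop("unknown event type: ", event$type)

  rownames(segs) <- NULL; rownames(sites) <- NULL
  stopifnot(nrow(sites) == nrow(segs) + 1L)
  state$segments <- segs
  state$sites <- sites
  state$events <- c(state$events, list(ev))
  state
}

#' Replay an event log from the reference
#' @param chrom a `synthetic_chromosome`.
#' @param events list of events (`type`, `i`, `j`).
#' @param episomes episomes present.
#' @return a `chromosome_state`.
#' @export
replay_events <- function(chrom, events, episomes = character()) {
  state <- new_state(chrom, episomes)
  for (ev in events) state <- apply_event(state, ev)
  state
}

#' Sample Cre recombination events for a fixed chromosome state
#'
#' Site pairs are drawn with probability proportional to `weights[i, j]`;
#' event types are drawn independently from `type_probs`. The draws are
#' i.i.d. for the given state; sequential application with re-weighting is
#' what [simulate_population] does.
#'
#' @param state a `chromosome_state`.
#' @param n_events number of events to draw.
#' @param weights symmetric weight matrix over the current sites (e.g. from
#'   [weights_for_sites]).
#' @param type_probs named numeric summing to 1 over
#'   deletion/inversion/duplication.
#' @return list of `recombination_event`s.
#' @export
sample_events <- function(state, n_events, weights,
                          type_probs = c(deletion = 0.45, inversion = 0.45,
                                         duplication = 0.10)) {
  ns <- nrow(state$sites)
  if (!all(dim(weights) == ns)) stop("weight matrix does not match site count")
  ut <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[ut]
  if (all(w <= 0)) stop("all pair weights are zero")
  if (abs(sum(type_probs) - 1) > 1e-8) stop("type_probs must sum to 1")
  ks <- sample.int(nrow(ut), n_events, replace = TRUE, prob = w)
  types <- sample(names(type_probs), n_events, replace = TRUE,
                  prob = type_probs)
  lapply(seq_len(n_events), function(q) {
    recombination_event(types[q], ut[ks[q], 1L], ut[ks[q], 2L])
  })
}

#' Simulate SCRaMbLE across a population of cells
#'
#' Each cell receives a Poisson(`lambda_events`) number of Cre events,
#' applied sequentially; pair weights are recomputed on the current layout
#' after every event (the hic_contact model instead looks up static
#' reference contacts, which is exact only for the first event on an
#' unrearranged strain).
#'
#' @param chrom a `synthetic_chromosome` (typically URA3-integrated).
#' @param n_cells population size.
#' @param lambda_events mean Cre events per induced cell (default 2).
#' @param type_probs event-type prior; deletions and inversions dominate,
#'   duplication is rare.
#' @param model,params,matrix,cids weight model arguments, see
#'   [weights_for_sites].
#' @param episomes episomes carried by every cell (e.g. `"eArray"`).
#' @param seed integer seed; the population is a pure function of it.
#' @return list of `strain` objects (`id`, `state`, `flags`), ids
#'   `S00001`...
#' @export
simulate_population <- function(chrom, n_cells, lambda_events = 2,
                                type_probs = c(deletion = 0.45,
                                               inversion = 0.45,
                                               duplication = 0.10),
                                model = "power_law",
                                params = default_weight_params(),
                                matrix = NULL, cids = NULL,
                                episomes = character(), seed = 1L) {
  if (n_cells < 1L) stop("n_cells must be >= 1")
  set.seed(seed)
  base <- new_state(chrom, episomes)
  counts <- rpois(n_cells, lambda_events)
  lapply(seq_len(n_cells), function(c_i) {
    state <- base
    n_ev <- counts[c_i]
    for (q in seq_len(n_ev)) {
      if (nrow(state$segments) < 1L) break
      w <- weights_for_sites(state, model, params, matrix, cids)
      if (all(w[upper.tri(w)] <= 0)) break
      ev <- sample_events(state, 1L, w, type_probs)[[1L]]
      state <- apply_event(state, ev)
    }
    structure(list(id = sprintf("S%05d", c_i), state = state,
                   flags = list()), class = "strain")
  })
}

#' @export
print.strain <- function(x, ...) {
  cat(sprintf("strain %s: %d segments, %d events\n", x$id,
              nrow(x$state$segments), length(x$state$events)))
  invisible(x)
}

#' Write strain event logs as JSON lines
#'
#' One line per event: strain id, order, type and the 1-based site indices
#' at application time, plus the LU refs the event touched.
#' @param strains list of `strain`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(strains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in strains) {
    for (ev in s$state$events) {
      writeLines(jsonlite::toJSON(
        list(strain = s$id, order = ev$order, type = ev$type,
             i = ev$i, j = ev$j, lus = ev$lus), auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}
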