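#' Rank candidate LUs for URA3 reporter integration
#'
#' Candidates are LUs carrying no essential gene, no quasi-essential
#' (growth-critical) gene and not the centromere. When a CID segmentation
#' is supplied they are ranked by the bp span of the domain containing the
#' LU midpoint (larger domains allow larger reporter-anchored deletions);
#' without one, by the bp span of the contiguous run of candidate LUs
#' around each candidate.
#'
#' @param chrom a `synthetic_chromosome`.
#' @param cids optional `cid_segmentation` on reference coordinates.
#' @return data.frame `lu_id`, `span_bp`, sorted by decreasing span.
#' @export
rank_ura3_sites <- function(chrom, cids = NULL) {
  lt <- lu_table(chrom)
  cand <- !lt$has_essential & !lt$has_quasi & !lt$has_centromere
  if (!any(cand)) stop("no candidate LU for reporter integration")
  mid <- (lt$start + lt$end) / 2
  if (!is.null(cids)) {
    dom <- cid_of_position(cids, mid)
    span <- (cids$domains$end_bp - cids$domains$start_bp)[dom]
  } else {
    r <- rle(cand)
    run_id <- rep(seq_along(r$lengths), r$lengths)
    run_bp <- tapply(lt$length_bp, run_id, sum)
    span <- as.numeric(run_bp[run_id])
  }
  out <- data.frame(lu_id = lt$lu_id[cand], span_bp = span[cand],
                    stringsAsFactors = FALSE)
  out[order(-out$span_bp, out$lu_id), , drop = FALSE]
}

#' Default per-round configuration
#'
#' @param ura3_target NULL (reporter already integrated) or a list with
#'   `lu`, `mode` and the mode's argument (`gene_id`, `between` or
#'   `offsets`).
#' @param earray an `earray` object carried by every cell, or NULL.
#' @param n_cells induced population size.
#' @param lambda_events mean Cre events per cell.
#' @param model,params proximity weight model (see [weights_for_sites]).
#' @param type_probs event-type prior.
#' @param medium plating medium.
#' @param top_k strains carried forward.
#' @param seed round seed.
#' @param matrix,cids optional Hi-C inputs for the weight model.
#' @param condition active growth condition.
#' @return a `round_config` list.
#' @export
round_config <- function(ura3_target = NULL, earray = NULL,
                         n_cells = 1000L, lambda_events = 2,
                         model = "cid_boost",
                         params = default_weight_params(),
                         type_probs = c(deletion = 0.45, inversion = 0.45,
                                        duplication = 0.10),
                         medium = "5FOA", top_k = 3L, seed = 1L,
                         matrix = NULL, cids = NULL, condition = "YPD30") {
  structure(list(ura3_target = ura3_target, earray = earray,
                 n_cells = n_cells, lambda_events = lambda_events,
                 model = model, params = params, type_probs = type_probs,
                 medium = medium, top_k = top_k, seed = seed,
                 matrix = matrix, cids = cids, condition = condition),
            class = "round_config")
}

.integrate_target <- function(chrom, tgt) {
  if (is.null(tgt)) return(chrom)
  integrate_ura3(chrom, tgt$lu, tgt$mode, gene_id = tgt$gene_id,
                 between = tgt$between, offsets = tgt$offsets)
}

#' Run one round of SCRaMbLE-based genome compaction
#'
#' Integrates the URA3 reporter, simulates the induced population, applies
#' 5-FOA/viability selection, profiles every survivor and ranks them by
#' deleted bp (ties: fewer non-deletion events, then strain id). An empty
#' plate is not an exception: it is returned as a structured "no colonies"
#' result, which is diagnostic (it is the expected outcome when the
#' reporter sits beside an uncomplemented essential gene).
#'
#' @param chrom the round's reference `synthetic_chromosome`.
#' @param config a `round_config`.
#' @return an object of class `sgc_round`: either
#'   `list(no_colonies = TRUE, diagnosis, chrom)` or a list with `chrom`
#'   (reporter-integrated reference), `survivors`, `profiles`, `stats`
#'   (data.frame, ranked), `chosen` (top strain ids), `n_simulated`,
#'   `n_survivors`.
#' @export
run_round <- function(chrom, config) {
  chrom2 <- .integrate_target(chrom, config$ura3_target)
  earray_present <- !is.null(config$earray)
  strains <- simulate_population(
    chrom2, n_cells = config$n_cells, lambda_events = config$lambda_events,
    type_probs = config$type_probs, model = config$model,
    params = config$params, matrix = config$matrix, cids = config$cids,
    episomes = if (earray_present) "eArray" else character(),
    seed = config$seed)
  survivors <- select_population(strains, earray = config$earray,
                                 medium = config$medium,
                                 condition = config$condition)
  message(sprintf("round: %d simulated, %d selected on %s",
                  length(strains), length(survivors), config$medium))
  if (!length(survivors)) {
    return(structure(list(
      no_colonies = TRUE, chrom = chrom2,
      diagnosis = paste("no colonies: every simulated genotype either",
                        "retained the reporter or required a gene lost with",
                        "it; genes in the reporter-carrying LU may be",
                        "required under the selection applied"),
      n_simulated = length(strains)), class = "sgc_round"))
  }
  profiles <- lapply(survivors, profile_from_state)
  stats <- do.call(rbind, lapply(seq_along(survivors), function(k) {
    st <- compaction_stats(profiles[[k]], chrom2)
    ev <- survivors[[k]]$state$events
    data.frame(strain = survivors[[k]]$id,
               n_lus_deleted = st$n_lus_deleted,
               bp_deleted = st$bp_deleted,
               n_genes_deleted = st$n_genes_deleted,
               n_events = length(ev),
               n_non_deletion = sum(vapply(ev, `[[`, "", "type") != "deletion"),
               deleted_lus = paste(st$deleted_lus, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  ord <- order(-stats$bp_deleted, stats$n_non_deletion, stats$strain)
  stats <- stats[ord, , drop = FALSE]
  rownames(stats) <- NULL
  chosen <- head(stats$strain, config$top_k)
  structure(list(no_colonies = FALSE, chrom = chrom2,
                 survivors = survivors[ord], profiles = profiles[ord],
                 stats = stats, chosen = chosen,
                 n_simulated = length(strains),
                 n_survivors = length(survivors)), class = "sgc_round")
}

#' @export
print.sgc_round <- function(x, ...) {
  if (isTRUE(x$no_colonies)) {
    cat("sgc_round: NO COLONIES -", x$diagnosis, "\n")
  } else {
    cat(sprintf("sgc_round: %d/%d survivors; best strain %s deleted %d LUs / %s bp\n",
                x$n_survivors, x$n_simulated, x$stats$strain[1L],
                x$stats$n_lus_deleted[1L],
                format(x$stats$bp_deleted[1L], big.mark = ",")))
  }
  invisible(x)
}

#' Rebuild a reference chromosome from a strain's retained structure
#'
#' The surviving segments become the LUs of a new reference, in their
#' current order; inverted copies are re-oriented (gene strands flipped,
#' sequence reverse complemented) so the new reference reads forward.
#' Duplicated copies are renamed `<lu>+dupN` with their genes suffixed
#' alike. The reporter marker is dropped if its LU was lost.
#'
#' @param state a `chromosome_state` (must carry exactly one centromere
#'   copy if the reference models one).
#' @param name name of the derived chromosome.
#' @return a `synthetic_chromosome`.
#' @export
collapse_state <- function(state, name = NULL) {
  chrom <- state$chrom
  seg <- state$segments
  if (!nrow(seg)) stop("cannot collapse an empty chromosome state")
  if (is.null(name)) name <- paste0(chrom$name, "+", length(state$events), "ev")
  copy_n <- stats::ave(seq_len(nrow(seg)), seg$lu, FUN = seq_along)
  new_ids <- ifelse(copy_n == 1L, seg$lu,
                    paste0(seg$lu, "+dup", copy_n - 1L))
  len <- setNames(chrom$lus$length_bp, chrom$lus$lu_id)
  lus <- data.frame(lu_id = new_ids, length_bp = unname(len[seg$lu]),
                    stringsAsFactors = FALSE)
  genes <- list()
  for (k in seq_len(nrow(seg))) {
    g <- chrom$genes[chrom$genes$lu_id == seg$lu[k], , drop = FALSE]
    if (!nrow(g)) next
    L <- len[[seg$lu[k]]]
    if (seg$orient[k] == "-") {
      rs <- L - g$rel_end
      g$rel_end <- L - g$rel_start
      g$rel_start <- rs
      g$strand <- ifelse(g$strand == "+", "-", "+")
    }
    g$lu_id <- new_ids[k]
    if (copy_n[k] > 1L) g$id <- paste0(g$id, "+dup", copy_n[k] - 1L)
    genes[[length(genes) + 1L]] <- g
  }
  genes <- if (length(genes)) do.call(rbind, genes) else NULL
  cen <- NULL
  if (!is.null(chrom$centromere)) {
    k <- which(seg$lu == chrom$centromere$lu_id)
    if (length(k) != 1L) stop("collapsed state must carry exactly one centromere")
    cen <- chrom$centromere
    if (seg$orient[k] == "-") {
      L <- len[[cen$lu_id]]
      cen <- list(lu_id = new_ids[k], rel_start = L - cen$rel_end,
                  rel_end = L - cen$rel_start)
    } else cen$lu_id <- new_ids[k]
  }
  lu_seqs <- NULL
  if (!is.null(chrom$lu_seqs)) {
    lu_seqs <- setNames(vapply(seq_len(nrow(seg)), function(k) {
      s <- chrom$lu_seqs[[seg$lu[k]]]
      if (seg$orient[k] == "-") {
        s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      }
      s
    }, ""), new_ids)
  }
  markers <- chrom$markers
  if (!is.null(markers$URA3) && !markers$URA3 %in% new_ids) markers$URA3 <- NULL
  synthetic_chromosome(name, lus, genes, cen, markers, lu_seqs)
}

#' Run iterative SGC rounds end-to-end
#'
#' Each round starts from the previous round's top strain: its retained
#' structure becomes the next reference, the next reporter is integrated,
#' and the ledger accumulates the deletions. Stops early (with the ledger
#' so far) when a round yields no colonies.
#'
#' @param chrom the original reference `synthetic_chromosome`.
#' @param rounds list of `round_config`s.
#' @return list with `ledger` (`compaction_ledger`), `lineage` (data.frame
#'   `round_id`, `strain`), `final_chrom`, `rounds` (the `sgc_round`
#'   results) and `stopped_early`.
#' @export
run_iterative <- function(chrom, rounds) {
  if (!length(rounds)) stop("need at least one round")
  ledger <- new_ledger(chrom)
  current <- chrom
  lineage <- list(); results <- list()
  for (r in seq_along(rounds)) {
    res <- run_round(current, rounds[[r]])
    results[[r]] <- res
    if (isTRUE(res$no_colonies)) {
      return(list(ledger = ledger,
                  lineage = do.call(rbind, lineage), final_chrom = current,
                  rounds = results, stopped_early = TRUE))
    }
    best <- res$survivors[[1L]]
    prof <- res$profiles[[1L]]
    deleted <- prof$status$lu_id[prof$status$deleted]
    ledger <- update_ledger(ledger, list(round_id = paste0("R", r),
                                         strain = best$id,
                                         deleted_lus = deleted,
                                         chrom = res$chrom))
    lineage[[r]] <- data.frame(round_id = paste0("R", r), strain = best$id,
                               stringsAsFactors = FALSE)
    current <- collapse_state(best$state,
                              name = paste0(chrom$name, "-R", r))
  }
  list(ledger = ledger, lineage = do.call(rbind, lineage),
       final_chrom = current, rounds = results, stopped_early = FALSE)
}
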