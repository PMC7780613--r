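#' Start a compaction ledger against a reference arm
#'
#' The ledger records, per SGC round, the LUs deleted with their bp and
#' gene counts, and maintains the cumulative retained totals against the
#' original reference. Sub-LUs created by reporter integration (e.g.
#' `LU-24-b`) are attributed to their parent unit: an original LU counts as
#' deleted only once all of its parts are gone.
#'
#' @param chrom the original reference `synthetic_chromosome`.
#' @return an object of class `compaction_ledger`.
#' @export
new_ledger <- function(chrom) {
  s <- lu_stats(chrom)
  structure(list(
    reference = list(n_lus = s$n_lus, total_bp = s$total_synthetic_bp,
                     n_genes = s$n_genes,
                     lu_ids = chrom$lus$lu_id),
    rounds = data.frame(round_id = character(), strain = character(),
                        n_lus_deleted = integer(), bp_deleted = integer(),
                        n_genes_deleted = integer(), deleted_lus = character(),
                        stringsAsFactors = FALSE),
    deleted_ids = character()), class = "compaction_ledger")
}

#' Record one SGC round in the ledger
#'
#' @param ledger a `compaction_ledger`.
#' @param round_result list with `round_id`, `strain` (id), `deleted_lus`
#'   (character vector of LU ids deleted this round, sub-LU ids allowed)
#'   and `chrom` (the reference in force during the round, used to look up
#'   lengths and gene content of the deleted ids).
#' @return the updated ledger.
#' @export
update_ledger <- function(ledger, round_result) {
  del <- round_result$deleted_lus
  chrom <- round_result$chrom
  if (!all(del %in% chrom$lus$lu_id)) {
    stop("deleted LU ids not present in the round's reference: ",
         paste(setdiff(del, chrom$lus$lu_id), collapse = ", "))
  }
  overlap <- intersect(del, ledger$deleted_ids)
  if (length(overlap)) {
    stop("round deletions overlap earlier rounds: ",
         paste(overlap, collapse = ", "))
  }
  lt <- lu_table(chrom)
  bp <- sum(lt$length_bp[lt$lu_id %in% del])
  genes <- sum(chrom$genes$lu_id %in% del)
  # count whole original units: a parent is deleted this round if this
  # round removed its last surviving part
  cum_del <- c(ledger$deleted_ids, del)
  fully_deleted <- function(ids) {
    vapply(unique(parent_lu(ids)), function(p) {
      parts <- chrom$lus$lu_id[parent_lu(chrom$lus$lu_id) == p]
      if (!length(parts)) parts <- p
      all(parts %in% cum_del)
    }, FALSE)
  }
  newly_whole <- sum(fully_deleted(del))
  ledger$rounds <- rbind(ledger$rounds, data.frame(
    round_id = as.character(round_result$round_id),
    strain = as.character(round_result$strain),
    n_lus_deleted = as.integer(newly_whole), bp_deleted = as.integer(bp),
    n_genes_deleted = as.integer(genes),
    deleted_lus = paste(del, collapse = ";"), stringsAsFactors = FALSE))
  ledger$deleted_ids <- cum_del
  ledger
}

#' Cumulative retained totals of a ledger
#' @param ledger a `compaction_ledger`.
#' @return list `retained_lus`, `retained_bp`, `retained_genes`,
#'   `deleted_lus`, `deleted_bp`, `deleted_genes`.
#' @export
ledger_cumulative <- function(ledger) {
  d_lus <- sum(ledger$rounds$n_lus_deleted)
  d_bp <- sum(ledger$rounds$bp_deleted)
  d_genes <- sum(ledger$rounds$n_genes_deleted)
  list(retained_lus = ledger$reference$n_lus - d_lus,
       retained_bp = ledger$reference$total_bp - d_bp,
       retained_genes = ledger$reference$n_genes - d_genes,
       deleted_lus = d_lus, deleted_bp = d_bp, deleted_genes = d_genes)
}

#' @export
print.compaction_ledger <- function(x, ...) {
  cum <- ledger_cumulative(x)
  cat(sprintf("compaction_ledger: %d round(s); retained %d/%d LUs, %s/%s bp, %d/%d genes\n",
              nrow(x$rounds), cum$retained_lus, x$reference$n_lus,
              format(cum$retained_bp, big.mark = ","),
              format(x$reference$total_bp, big.mark = ","),
              cum$retained_genes, x$reference$n_genes))
  invisible(x)
}

#' Write a ledger as TSV (rounds) and JSON (rounds + cumulative)
#' @param ledger a `compaction_ledger`.
#' @param path_tsv,path_json output files (either may be NULL).
#' @return invisibly, the ledger.
#' @export
write_ledger <- function(ledger, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    write.table(ledger$rounds, path_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(reference = ledger$reference[1:3],
                              rounds = ledger$rounds,
                              cumulative = ledger_cumulative(ledger)),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(ledger)
}
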