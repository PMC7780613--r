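#' Viability and selection assessment of a strain
#'
#' Copy numbers of every essential gene are counted over the chromosome
#' segments, plus the eArray gene set when the episome is present. A strain
#' is viable iff no essential gene is missing and exactly one centromere is
#' carried (a duplication spanning the centromere yields a dicentric
#' chromosome and is scored inviable; when the reference models no
#' centromere inside the arm, the centromere sits on the unmodeled portion
#' and counts as one). Loss of any quasi-essential gene sets `slow_growth`;
#' loss of a condition-tagged gene under the active condition sets a
#' conditional defect. 5-FOA resistance requires the URA3 reporter to be
#' absent from all segments. Genes replaced by the reporter are absent from
#' every strain.
#'
#' @param strain a `strain` or `chromosome_state`.
#' @param earray the `earray` object carried episomally, or NULL;
#'   complementation only applies when the strain carries the `"eArray"`
#'   episome or `earray_present` is TRUE.
#' @param earray_present force eArray presence (default: taken from the
#'   state's episome set).
#' @param condition active growth condition label (default `"YPD30"`,
#'   which imposes no conditional requirement).
#' @return a `viability_report` list: `viable`, `missing_essential`,
#'   `centromere_count`, `slow_growth`, `foa_resistant`,
#'   `conditional_defect`.
#' @export
assess <- function(strain, earray = NULL, earray_present = NULL,
                   condition = "YPD30") {
  state <- if (inherits(strain, "strain")) strain$state else strain
  chrom <- state$chrom
  if (is.null(earray_present)) earray_present <- "eArray" %in% state$episomes
  present_lus <- state$segments$lu
  g <- chrom$genes[!chrom$genes$replaced, , drop = FALSE]
  on_chrom <- g$lu_id %in% present_lus

  ess <- g$essentiality == "essential"
  covered <- if (earray_present && !is.null(earray)) g$id %in% earray$gene_ids
             else rep(FALSE, nrow(g))
  missing <- g$id[ess & !on_chrom & !covered]

  cen_lu <- if (is.null(chrom$centromere)) NULL else chrom$centromere$lu_id
  cen_count <- if (is.null(cen_lu)) 1L else sum(present_lus == cen_lu)

  quasi_missing <- g$id[g$essentiality == "quasi_essential" & !on_chrom]
  cond_missing <- g$id[!on_chrom & g$conditional != "" &
                         vapply(g$conditional, function(x) {
                           condition %in% strsplit(x, ";", fixed = TRUE)[[1L]]
                         }, FALSE)]
  ura3_lu <- chrom$markers$URA3
  ura3_present <- !is.null(ura3_lu) && ura3_lu %in% present_lus

  structure(list(viable = length(missing) == 0L && cen_count == 1L,
                 missing_essential = missing,
                 centromere_count = cen_count,
                 slow_growth = length(quasi_missing) > 0L,
                 foa_resistant = !ura3_present,
                 conditional_defect = cond_missing),
            class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat(sprintf("viability_report: %s, cen=%d, 5-FOA %s%s\n",
              if (x$viable) "viable" else
                paste0("inviable (missing ",
                       paste(x$missing_essential, collapse = ","), ")"),
              x$centromere_count,
              if (x$foa_resistant) "resistant" else "sensitive",
              if (x$slow_growth) ", slow growth" else ""))
  invisible(x)
}

#' Apply plating selection to a simulated population
#'
#' Keeps viable strains; on 5-FOA medium, survivors must additionally have
#' lost the URA3 reporter. SC and YPD impose viability only.
#'
#' @param strains list of `strain`s.
#' @param earray `earray` object or NULL.
#' @param medium `"5FOA"`, `"SC"` or `"YPD"`.
#' @param condition active growth condition.
#' @return the surviving subset, each with `flags` filled from its
#'   viability report.
#' @export
select_population <- function(strains, earray = NULL,
                              medium = c("5FOA", "SC", "YPD"),
                              condition = "YPD30") {
  medium <- match.arg(medium)
  kept <- lapply(strains, function(s) {
    rep <- assess(s, earray = earray, condition = condition)
    if (!rep$viable) return(NULL)
    if (medium == "5FOA" && !rep$foa_resistant) return(NULL)
    s$flags <- list(slow_growth = rep$slow_growth,
                    conditional_defect = rep$conditional_defect)
    s
  })
  kept[!vapply(kept, is.null, FALSE)]
}

#' Exhaustively enumerate all viable single Cre deletions
#'
#' Brute-force oracle over all O(n^2) site pairs of the unrearranged
#' reference: for each pair the single-deletion product is built and
#' assessed; pairs whose product is viable (and 5-FOA-resistant when
#' required) are returned together with the LUs they excise.
#'
#' @param chrom a `synthetic_chromosome`.
#' @param earray `earray` or NULL.
#' @param earray_present does the strain carry the array episome.
#' @param require_5foa demand loss of the URA3 reporter.
#' @param condition active growth condition.
#' @return data.frame with `i`, `j` (1-based site indices) and
#'   `deleted_lus` (semicolon-joined LU ids); zero rows when nothing
#'   survives.
#' @export
enumerate_single_deletions <- function(chrom, earray = NULL,
                                       earray_present = FALSE,
                                       require_5foa = TRUE,
                                       condition = "YPD30") {
  base <- new_state(chrom, if (earray_present) "eArray" else character())
  ns <- nrow(base$sites)
  if (ns < 2L) stop("chromosome has fewer than two loxPsym sites")
  out <- list()
  for (i in seq_len(ns - 1L)) {
    for (j in seq.int(i + 1L, ns)) {
      st <- apply_event(base, recombination_event("deletion", i, j))
      rep <- assess(st, earray = earray, earray_present = earray_present,
                    condition = condition)
      if (!rep$viable) next
      if (require_5foa && !rep$foa_resistant) next
      out[[length(out) + 1L]] <- data.frame(
        i = i, j = j,
        deleted_lus = paste(st$events[[1L]]$lus, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(),
                      deleted_lus = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
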