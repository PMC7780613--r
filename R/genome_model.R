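# Length of the loxPsym recombination site. The 34-mer is palindromic, so it
# has no orientation and survives reverse complementation unchanged.
LOXPSYM_BP <- 34L
LOXPSYM_SEQ <- "ATAACTTCGTATAATGTACATTATACGAAGTTAT"

GENE_CLASSES <- c("essential", "quasi_essential", "nonessential")

#' Construct a synthetic chromosome arm from an ordered loxPsym-unit table
#'
#' The canonical internal representation of a synthetic arm is the ordered
#' list of loxPsym units (LUs) with their lengths, plus genes located by
#' LU-relative coordinates. Absolute coordinates are derived by laying the
#' arm out as `[site][LU-1][site][LU-2]...[LU-n][site]`, i.e. a 34-bp
#' loxPsym site flanks every LU, including both ends of the synthetic
#' region, so that every LU (terminal ones included) can take part in Cre
#' recombination.
#'
#' All coordinates are 0-based half-open. LU length accounting excludes the
#' loxPsym sites themselves: `sum(length_bp)` is the synthetic payload, and
#' deleted-sequence statistics downstream are sums of LU lengths.
#'
#' @param name chromosome name.
#' @param lus data.frame with columns `lu_id`, `length_bp`.
#' @param genes data.frame with columns `id`, `lu_id`, `rel_start`,
#'   `rel_end` (0-based, LU-relative), `strand` (`+`/`-`), `essentiality`
#'   (`essential`, `quasi_essential` or `nonessential`), and optionally
#'   `conditional` (semicolon-separated condition labels, "" for none) and
#'   `replaced` (logical; gene replaced by the URA3 reporter).
#' @param centromere list with `lu_id`, `rel_start`, `rel_end`.
#' @param markers named list; `URA3` holds the id of the LU carrying the
#'   reporter (or NULL).
#' @param lu_seqs optional named character vector of per-LU sequences
#'   (names = `lu_id`, `nchar` = `length_bp`).
#' @return an object of class `synthetic_chromosome`.
#' @export
synthetic_chromosome <- function(name, lus, genes, centromere,
                                 markers = list(URA3 = NULL),
                                 lu_seqs = NULL) {
  stopifnot(is.data.frame(lus), all(c("lu_id", "length_bp") %in% names(lus)))
  lus <- lus[, c("lu_id", "length_bp")]
  lus$length_bp <- as.integer(lus$length_bp)
  if (anyDuplicated(lus$lu_id)) stop("duplicated LU ids")
  if (any(lus$length_bp <= 0L)) stop("LU lengths must be positive")

  if (is.null(genes) || nrow(genes) == 0L) {
    genes <- data.frame(id = character(), lu_id = character(),
                        rel_start = integer(), rel_end = integer(),
                        strand = character(), essentiality = character(),
                        conditional = character(), replaced = logical(),
                        stringsAsFactors = FALSE)
  }
  if (is.null(genes$conditional)) genes$conditional <- ""
  if (is.null(genes$replaced)) genes$replaced <- FALSE
  genes$conditional[is.na(genes$conditional)] <- ""
  bad <- setdiff(genes$essentiality, GENE_CLASSES)
  if (length(bad)) stop("unknown essentiality class: ", paste(bad, collapse = ", "))
  if (!all(genes$lu_id %in% lus$lu_id)) {
    stop("gene assigned to unknown LU: ",
         paste(setdiff(genes$lu_id, lus$lu_id), collapse = ", "))
  }
  len <- stats::setNames(lus$length_bp, lus$lu_id)
  if (any(genes$rel_start < 0L) || any(genes$rel_end > len[genes$lu_id])) {
    stop("gene outside its LU")
  }
  if (any(genes$rel_start >= genes$rel_end)) stop("empty gene interval")

  # centromere == NULL models an arm whose centromere lies on the unmodeled
  # wild-type part of the chromosome (toy fixtures)
  if (!is.null(centromere)) {
    if (!centromere$lu_id %in% lus$lu_id) stop("centromere LU not found")
    if (centromere$rel_start < 0L ||
        centromere$rel_end > len[[centromere$lu_id]]) {
      stop("centromere outside its LU")
    }
  }

  if (!is.null(lu_seqs)) {
    if (!setequal(names(lu_seqs), lus$lu_id)) stop("lu_seqs names must match LU ids")
    if (any(nchar(lu_seqs[lus$lu_id]) != lus$length_bp)) {
      stop("lu_seqs lengths disagree with LU lengths")
    }
    lu_seqs <- lu_seqs[lus$lu_id]
  }

  obj <- structure(list(name = name, lus = lus, genes = genes,
                        centromere = centromere, markers = markers,
                        lu_seqs = lu_seqs, loxpsym_bp = LOXPSYM_BP),
                   class = "synthetic_chromosome")
  validate_chromosome(obj)
  obj
}

#' Assert the structural invariants of a synthetic chromosome
#'
#' Checks the LU tiling (sites + LU lengths account for the full region),
#' gene containment, single-LU centromere and gene class validity. Called
#' by every constructor; exported because state-manipulating code calls it
#' after rebuilding a chromosome.
#'
#' @param chrom a `synthetic_chromosome`.
#' @return `chrom`, invisibly.
#' @export
validate_chromosome <- function(chrom) {
  lt <- lu_table(chrom)
  n <- nrow(lt)
  st <- site_table(chrom)
  stopifnot(nrow(st) == n + 1L)
  # tiling: LU k spans from the end of site k-1 to the start of site k
  stopifnot(all(lt$start == st$position[-(n + 1L)] + chrom$loxpsym_bp))
  stopifnot(all(lt$end == st$position[-1L]))
  stopifnot(sum(lt$length_bp) == lt$end[n] - lt$start[1L] -
              (n - 1L) * chrom$loxpsym_bp)
  if (!is.null(chrom$centromere)) {
    cen <- which(lt$has_centromere)
    if (length(cen) != 1L) stop("centromere must lie in exactly one LU")
  }
  invisible(chrom)
}

#' LU table with absolute coordinates and annotation flags
#'
#' @param chrom a `synthetic_chromosome`.
#' @return data.frame with `lu_id`, `start`, `end` (absolute, 0-based
#'   half-open, loxPsym sites excluded from the interval), `length_bp`,
#'   `n_genes`, `has_essential` (contains a strictly essential gene),
#'   `has_quasi`, `has_centromere`, `has_ura3`.
#' @export
lu_table <- function(chrom) {
  lus <- chrom$lus
  n <- nrow(lus)
  start <- chrom$loxpsym_bp +
    cumsum(c(0L, lus$length_bp[-n] + chrom$loxpsym_bp))
  g <- chrom$genes
  cnt <- table(factor(g$lu_id, levels = lus$lu_id))
  ess <- tapply(g$essentiality == "essential",
                factor(g$lu_id, levels = lus$lu_id), any)
  qua <- tapply(g$essentiality == "quasi_essential",
                factor(g$lu_id, levels = lus$lu_id), any)
  ura3 <- chrom$markers$URA3
  data.frame(lu_id = lus$lu_id, start = as.integer(start),
             end = as.integer(start + lus$length_bp),
             length_bp = lus$length_bp,
             n_genes = as.integer(cnt),
             has_essential = !is.na(ess) & ess,
             has_quasi = !is.na(qua) & qua,
             has_centromere = if (is.null(chrom$centromere)) rep(FALSE, n) else
               lus$lu_id == chrom$centromere$lu_id,
             has_ura3 = if (is.null(ura3)) rep(FALSE, n) else lus$lu_id == ura3,
             stringsAsFactors = FALSE)
}

#' loxPsym site table
#'
#' @param chrom a `synthetic_chromosome`.
#' @return data.frame with `index` (0-based) and `position` (0-based start
#'   of the 34-bp site).
#' @export
site_table <- function(chrom) {
  lus <- chrom$lus
  n <- nrow(lus)
  pos <- cumsum(c(0L, lus$length_bp + chrom$loxpsym_bp))
  data.frame(index = 0:n, position = as.integer(pos))
}

#' Gene table with absolute coordinates
#'
#' @param chrom a `synthetic_chromosome`.
#' @return data.frame of genes with absolute `start`/`end` added.
#' @export
gene_table <- function(chrom) {
  g <- chrom$genes
  lt <- lu_table(chrom)
  off <- stats::setNames(lt$start, lt$lu_id)
  g$start <- as.integer(off[g$lu_id] + g$rel_start)
  g$end <- as.integer(off[g$lu_id] + g$rel_end)
  g[order(g$start), , drop = FALSE]
}

#' Total extent of the arm including loxPsym sites
#' @param chrom a `synthetic_chromosome`.
#' @return length in bp.
#' @export
region_length <- function(chrom) {
  sum(chrom$lus$length_bp) + (nrow(chrom$lus) + 1L) * chrom$loxpsym_bp
}

#' @export
print.synthetic_chromosome <- function(x, ...) {
  s <- lu_stats(x)
  cat(sprintf("synthetic_chromosome '%s': %d LUs (%d with essential genes), %d genes, %s bp synthetic sequence\n",
              x$name, s$n_lus, s$n_essential_lus, s$n_genes,
              format(s$total_synthetic_bp, big.mark = ",")))
  invisible(x)
}

#' Segment a region into loxPsym units
#'
#' Given the loxPsym site positions flanking and subdividing a synthetic
#' region, builds the LU tiling and assigns genes to units. A gene that
#' crosses a loxPsym site is an error: genes must be wholly contained in a
#' single unit.
#'
#' @param sites integer vector of 0-based start positions of the 34-bp
#'   loxPsym sites, strictly increasing; the first must sit at the region
#'   start and the last must end at the region end.
#' @param region integer length-2 vector `c(start, end)`, 0-based half-open.
#' @param genes data.frame with absolute `start`, `end`, `id`, `strand`,
#'   `essentiality` (plus optional `conditional`, `replaced`).
#' @param centromere length-2 vector `c(start, end)` in absolute coords.
#' @param lu_ids optional character vector of LU ids (default `LU-1` ...).
#' @param site_bp loxPsym site length (34).
#' @return data.frame of LUs (`lu_id`, `start`, `end`, `length_bp`).
#' @export
segment_lus <- function(sites, region, genes = NULL, centromere = NULL,
                        lu_ids = NULL, site_bp = LOXPSYM_BP) {
  sites <- as.integer(sites)
  if (length(sites) < 2L) stop("need at least two loxPsym sites")
  if (is.unsorted(sites, strictly = TRUE)) stop("loxPsym sites must be strictly increasing")
  if (sites[1L] != region[1L]) stop("first site must sit at the region start")
  if (sites[length(sites)] + site_bp != region[2L]) {
    stop("last site must end at the region end")
  }
  n <- length(sites) - 1L
  start <- sites[-(n + 1L)] + site_bp
  end <- sites[-1L]
  if (any(end <= start)) stop("adjacent loxPsym sites leave no unit between them")
  if (is.null(lu_ids)) lu_ids <- paste0("LU-", seq_len(n))
  lus <- data.frame(lu_id = lu_ids, start = as.integer(start),
                    end = as.integer(end),
                    length_bp = as.integer(end - start),
                    stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(genes)) {
    idx <- findInterval(genes$start, lus$start)
    bad <- idx < 1L | genes$start < lus$start[pmax(idx, 1L)] |
      genes$end > lus$end[pmax(idx, 1L)]
    if (any(bad)) {
      stop("gene(s) cross a loxPsym site or fall outside the region: ",
           paste(genes$id[bad], collapse = ", "))
    }
  }
  if (!is.null(centromere)) {
    idx <- findInterval(centromere[1L], lus$start)
    if (idx < 1L || centromere[2L] > lus$end[idx]) {
      stop("centromere is not contained in a single LU")
    }
  }
  lus
}

#' Summary statistics of a synthetic chromosome's LU table
#'
#' @param chrom a `synthetic_chromosome`.
#' @return list with `n_lus`, `n_essential_lus`, `n_genes`, `n_essential`,
#'   `n_nonessential` (quasi-essential genes are counted here as in the
#'   published totals, and also reported separately as `n_quasi`),
#'   `min_lu_bp`, `max_lu_bp`, `max_genes_per_lu`, `total_synthetic_bp`.
#' @export
lu_stats <- function(chrom) {
  lt <- lu_table(chrom)
  g <- chrom$genes
  n_ess <- sum(g$essentiality == "essential")
  list(n_lus = nrow(lt),
       n_essential_lus = sum(lt$has_essential),
       n_genes = nrow(g),
       n_essential = n_ess,
       n_nonessential = nrow(g) - n_ess,
       n_quasi = sum(g$essentiality == "quasi_essential"),
       min_lu_bp = min(lt$length_bp),
       max_lu_bp = max(lt$length_bp),
       max_genes_per_lu = max(lt$n_genes),
       total_synthetic_bp = sum(lt$length_bp))
}

#' Integrate the URA3 counterselection reporter into a loxPsym unit
#'
#' Three integration modes mirror how the reporter cassette can be placed:
#' \describe{
#'   \item{replace_gene}{the reporter replaces a nonessential gene; the
#'     gene is flagged `replaced` (it remains in the reference gene table so
#'     deletion statistics still count it, but it is absent from every
#'     strain).}
#'   \item{insert_between}{the reporter is inserted between two adjacent
#'     genes of the target LU; gene content is unchanged.}
#'   \item{chunk_split}{integration introduces two additional loxPsym sites
#'     at the given offsets inside the target LU, splitting it into three
#'     sub-units named `<lu>-a`, `<lu>-b`, `<lu>-c`, with the reporter in
#'     the middle one. The LU table is re-segmented.}
#' }
#'
#' @param chrom a `synthetic_chromosome`.
#' @param target_lu id of the LU receiving the reporter.
#' @param mode one of `"replace_gene"`, `"insert_between"`, `"chunk_split"`.
#' @param gene_id gene to replace (replace_gene mode).
#' @param between character length-2, the two adjacent gene ids
#'   (insert_between mode).
#' @param offsets integer length-2, split offsets relative to the LU start,
#'   `0 < offsets[1] < offsets[2] < length_bp` (chunk_split mode).
#' @return a new `synthetic_chromosome` with `markers$URA3` set.
#' @export
integrate_ura3 <- function(chrom, target_lu,
                           mode = c("replace_gene", "insert_between", "chunk_split"),
                           gene_id = NULL, between = NULL, offsets = NULL) {
  mode <- match.arg(mode)
  if (!target_lu %in% chrom$lus$lu_id) stop("target LU not found: ", target_lu)
  genes <- chrom$genes

  if (mode == "replace_gene") {
    k <- which(genes$id == gene_id)
    if (length(k) != 1L) stop("gene not found: ", gene_id)
    if (genes$lu_id[k] != target_lu) stop(gene_id, " is not in ", target_lu)
    if (genes$essentiality[k] != "nonessential") {
      stop("cannot replace non-dispensable gene ", gene_id, " with the reporter")
    }
    genes$replaced[k] <- TRUE
    out <- chrom
    out$genes <- genes
    out$markers$URA3 <- target_lu
    return(validate_chromosome(out))
  }

  if (mode == "insert_between") {
    ka <- which(genes$id == between[1L]); kb <- which(genes$id == between[2L])
    if (length(ka) != 1L || length(kb) != 1L) stop("insert_between genes not found")
    if (genes$lu_id[ka] != target_lu || genes$lu_id[kb] != target_lu) {
      stop("both flanking genes must be in ", target_lu)
    }
    in_lu <- genes[genes$lu_id == target_lu, ]
    in_lu <- in_lu[order(in_lu$rel_start), ]
    ia <- match(between[1L], in_lu$id); ib <- match(between[2L], in_lu$id)
    if (abs(ia - ib) != 1L) stop("insert_between genes are not adjacent in ", target_lu)
    out <- chrom
    out$markers$URA3 <- target_lu
    return(validate_chromosome(out))
  }

  # chunk_split
  ti <- which(chrom$lus$lu_id == target_lu)
  L <- chrom$lus$length_bp[ti]
  offsets <- as.integer(offsets)
  if (length(offsets) != 2L || offsets[1L] <= 0L || offsets[2L] >= L ||
      offsets[1L] >= offsets[2L]) {
    stop("chunk_split offsets must satisfy 0 < o1 < o2 < LU length")
  }
  in_t <- genes$lu_id == target_lu
  cross <- in_t & ((genes$rel_start < offsets[1L] & genes$rel_end > offsets[1L]) |
                   (genes$rel_start < offsets[2L] & genes$rel_end > offsets[2L]))
  if (any(cross)) {
    stop("chunk_split offsets cut through gene(s): ",
         paste(genes$id[cross], collapse = ", "))
  }
  sub_ids <- paste0(target_lu, c("-a", "-b", "-c"))
  sub_len <- c(offsets[1L], offsets[2L] - offsets[1L], L - offsets[2L])
  lus <- chrom$lus
  lus <- rbind(lus[seq_len(ti - 1L), ],
               data.frame(lu_id = sub_ids, length_bp = as.integer(sub_len)),
               lus[seq_len(nrow(lus) - ti) + ti, ])
  sub_of <- function(rs) ifelse(rs < offsets[1L], 1L,
                         ifelse(rs < offsets[2L], 2L, 3L))
  which_sub <- sub_of(genes$rel_start[in_t])
  genes$lu_id[in_t] <- sub_ids[which_sub]
  genes$rel_start[in_t] <- genes$rel_start[in_t] -
    c(0L, offsets)[which_sub]
  genes$rel_end[in_t] <- genes$rel_end[in_t] - c(0L, offsets)[which_sub]
  cen <- chrom$centromere
  if (!is.null(cen) && cen$lu_id == target_lu) {
    if (sub_of(cen$rel_start) != sub_of(cen$rel_end - 1L)) {
      stop("chunk_split offsets cut through the centromere")
    }
    k <- sub_of(cen$rel_start)
    cen <- list(lu_id = sub_ids[k], rel_start = cen$rel_start - c(0L, offsets)[k],
                rel_end = cen$rel_end - c(0L, offsets)[k])
  }
  lu_seqs <- chrom$lu_seqs
  if (!is.null(lu_seqs)) {
    s <- lu_seqs[[target_lu]]
    add <- stats::setNames(c(substr(s, 1L, offsets[1L]),
                             substr(s, offsets[1L] + 1L, offsets[2L]),
                             substr(s, offsets[2L] + 1L, L)), sub_ids)
    lu_seqs <- c(lu_seqs[setdiff(names(lu_seqs), target_lu)], add)
  }
  markers <- chrom$markers
  markers$URA3 <- sub_ids[2L]
  synthetic_chromosome(chrom$name, lus, genes, cen, markers, lu_seqs)
}

#' Undo a chunk_split URA3 integration
#'
#' Merges the three `-a`/`-b`/`-c` sub-units of a previously split LU back
#' into the original unit, restoring the original boundaries and clearing
#' the reporter marker. Used mainly to check split/merge consistency.
#'
#' @param chrom a `synthetic_chromosome` containing `<parent>-a/-b/-c`.
#' @param parent_id the original LU id.
#' @return a `synthetic_chromosome`.
#' @export
merge_split_lu <- function(chrom, parent_id) {
  sub_ids <- paste0(parent_id, c("-a", "-b", "-c"))
  ki <- match(sub_ids, chrom$lus$lu_id)
  if (anyNA(ki) || any(diff(ki) != 1L)) stop("sub-LUs of ", parent_id, " not found")
  lens <- chrom$lus$length_bp[ki]
  lus <- chrom$lus
  lus$lu_id[ki[1L]] <- parent_id
  lus$length_bp[ki[1L]] <- sum(lens)
  lus <- lus[-ki[2:3], ]
  off <- c(0L, cumsum(lens)[1:2])
  genes <- chrom$genes
  for (k in 1:3) {
    sel <- genes$lu_id == sub_ids[k]
    genes$lu_id[sel] <- parent_id
    genes$rel_start[sel] <- genes$rel_start[sel] + off[k]
    genes$rel_end[sel] <- genes$rel_end[sel] + off[k]
  }
  cen <- chrom$centromere
  k <- if (is.null(cen)) NA_integer_ else match(cen$lu_id, sub_ids)
  if (!is.na(k)) {
    cen <- list(lu_id = parent_id, rel_start = cen$rel_start + off[k],
                rel_end = cen$rel_end + off[k])
  }
  lu_seqs <- chrom$lu_seqs
  if (!is.null(lu_seqs)) {
    merged <- stats::setNames(paste0(lu_seqs[[sub_ids[1L]]],
                                     lu_seqs[[sub_ids[2L]]],
                                     lu_seqs[[sub_ids[3L]]]), parent_id)
    lu_seqs <- c(lu_seqs[setdiff(names(lu_seqs), sub_ids)], merged)
  }
  markers <- chrom$markers
  if (!is.null(markers$URA3) && markers$URA3 %in% sub_ids) markers$URA3 <- NULL
  synthetic_chromosome(chrom$name, lus, genes, cen, markers, lu_seqs)
}

#' Map sub-LU ids back to their original parent LU id
#'
#' `LU-24-a` was created by splitting `LU-24`; for bookkeeping against the
#' original reference both map to `LU-24`. Ids without an `-a`/`-b`/`-c`
#' suffix are returned unchanged.
#'
#' @param lu_ids character vector.
#' @return character vector of parent ids.
#' @export
parent_lu <- function(lu_ids) sub("-[abc]$", "", lu_ids)

#' Design the episomal essential-gene array (eArray)
#'
#' Essential genes whose start lies before `region_cutoff_bp` are grouped
#' into loci: a maximal run of essential genes uninterrupted by a
#' nonessential coding sequence forms one locus. Each locus interval
#' extends from the inner boundary (end) of the nearest upstream
#' nonessential CDS to the inner boundary (start) of the nearest downstream
#' nonessential CDS, clipped to the containing LU so that no loxPsym site
#' is ever included in the array (the array must stay inert during
#' SCRaMbLE). Overlapping loci are merged.
#'
#' @param chrom a `synthetic_chromosome`.
#' @param region_cutoff_bp absolute coordinate; only essential genes
#'   starting before it are included.
#' @return an object of class `earray`: list with `gene_ids`, `loci`
#'   (data.frame `label`, `start`, `end`, `genes`), `marker = "HIS3"`,
#'   `contains_loxpsym = FALSE`.
#' @export
build_earray <- function(chrom, region_cutoff_bp) {
  if (region_cutoff_bp < 0 || region_cutoff_bp > region_length(chrom)) {
    stop("cutoff outside the synthetic region")
  }
  g <- gene_table(chrom)
  g <- g[!g$replaced, ]
  g <- g[order(g$start), ]
  ess <- g$essentiality == "essential"
  sel <- ess & g$start < region_cutoff_bp
  if (!any(sel)) {
    return(structure(list(gene_ids = character(),
                          loci = data.frame(label = character(),
                                            start = integer(), end = integer(),
                                            genes = character()),
                          marker = "HIS3", contains_loxpsym = FALSE),
                     class = "earray"))
  }
  lt <- lu_table(chrom)
  # runs of consecutive selected essential genes with no nonessential CDS
  # in between (quasi-essential genes count as interrupting CDSs: they are
  # not carried on the array)
  run_id <- cumsum(sel & !c(FALSE, sel[-length(sel)]))
  run_id[!sel] <- NA
  loci <- lapply(split(which(sel), run_id[sel]), function(idx) {
    first <- min(idx); last <- max(idx)
    lu <- g$lu_id[first]
    lu_row <- lt[lt$lu_id == lu, ]
    up <- which(!ess[seq_len(first - 1L)])
    dn <- which(!ess) ; dn <- dn[dn > last]
    start <- if (length(up)) max(g$end[max(up)], lu_row$start) else lu_row$start
    end <- if (length(dn)) min(g$start[min(dn)], lu_row$end) else lu_row$end
    list(start = start, end = end, genes = g$id[idx], lu = lu)
  })
  # merge overlapping loci (possible when two runs share flanking CDSs)
  loci <- loci[order(vapply(loci, `[[`, 0, "start"))]
  merged <- list(loci[[1L]])
  if (length(loci) > 1L) for (k in 2:length(loci)) {
    prev <- merged[[length(merged)]]
    cur <- loci[[k]]
    if (cur$start < prev$end && cur$lu == prev$lu) {
      prev$end <- max(prev$end, cur$end)
      prev$genes <- c(prev$genes, cur$genes)
      merged[[length(merged)]] <- prev
    } else merged <- c(merged, list(cur))
  }
  labels <- letters[seq_along(merged)]
  loci_df <- data.frame(label = labels,
                        start = vapply(merged, `[[`, 0, "start"),
                        end = vapply(merged, `[[`, 0, "end"),
                        genes = vapply(merged, function(l) paste(l$genes, collapse = ";"), ""),
                        stringsAsFactors = FALSE)
  structure(list(gene_ids = unlist(lapply(merged, `[[`, "genes"), use.names = FALSE),
                 loci = loci_df, marker = "HIS3", contains_loxpsym = FALSE),
            class = "earray")
}

#' @export
print.earray <- function(x, ...) {
  cat(sprintf("eArray: %d essential genes across %d loci (marker %s)\n",
              length(x$gene_ids), nrow(x$loci), x$marker))
  invisible(x)
}
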