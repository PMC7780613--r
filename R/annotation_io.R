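#' Read a synthetic chromosome annotation
#'
#' Two dialects are supported. The canonical TSV has one row per feature
#' with columns `feature` (`lu`, `gene`, `centromere` or `reporter`),
#' `lu_id`, `start`, `end` (0-based half-open absolute coordinates),
#' `gene_id`, `strand`, `essentiality`, `flags` (semicolon-separated;
#' condition labels such as `37C`/`YPG`, and `replaced_by_reporter`).
#' loxPsym sites are implied by the LU tiling: a 34-bp site precedes every
#' LU and closes the region after the last one. GFF3 input uses feature
#' types `gene`, `loxPsym_site`, `centromere` and `reporter` with 1-based
#' closed coordinates, converted on read.
#'
#' @param path annotation file.
#' @param format `"tsv"` or `"gff3"` (default guessed from the extension).
#' @param fasta optional FASTA file with the full arm sequence (loxPsym
#'   34-mers at the site positions); per-LU sequences are extracted.
#' @param name chromosome name (TSV carries none); default file stem.
#' @return a `synthetic_chromosome`.
#' @export
load_annotation <- function(path, format = NULL, fasta = NULL, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  format <- match.arg(format, c("tsv", "gff3"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  parsed <- if (format == "tsv") .read_annot_tsv(path) else .read_annot_gff3(path)

  lus_abs <- parsed$lus[order(parsed$lus$start), ]
  n <- nrow(lus_abs)
  if (n < 1L) stop("annotation contains no LUs")
  region <- c(lus_abs$start[1L] - LOXPSYM_BP, lus_abs$end[n] + LOXPSYM_BP)
  sites <- c(lus_abs$start - LOXPSYM_BP, lus_abs$end[n])
  if (is.null(parsed$centromere)) stop("annotation lacks a centromere feature")
  # validates tiling, gene containment, centromere containment
  seg <- segment_lus(sites, region, parsed$genes, parsed$centromere,
                     lu_ids = lus_abs$lu_id)
  g <- parsed$genes
  idx <- findInterval(g$start, seg$start)
  genes <- data.frame(id = g$id, lu_id = seg$lu_id[idx],
                      rel_start = g$start - seg$start[idx],
                      rel_end = g$end - seg$start[idx],
                      strand = g$strand, essentiality = g$essentiality,
                      conditional = g$conditional, replaced = g$replaced,
                      stringsAsFactors = FALSE)
  cen_idx <- findInterval(parsed$centromere[1L], seg$start)
  cen <- list(lu_id = seg$lu_id[cen_idx],
              rel_start = parsed$centromere[1L] - seg$start[cen_idx],
              rel_end = parsed$centromere[2L] - seg$start[cen_idx])
  markers <- list(URA3 = parsed$ura3_lu)
  lu_seqs <- NULL
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    full <- as.character(seqs[[1L]])
    lu_seqs <- setNames(substring(full, seg$start + 1L, seg$end), seg$lu_id)
  }
  synthetic_chromosome(name, seg[, c("lu_id", "length_bp")], genes,
                       cen, markers, lu_seqs)
}

.read_annot_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", quote = "",
                  stringsAsFactors = FALSE, comment.char = "#")
  need <- c("feature", "lu_id", "start", "end", "gene_id", "strand",
            "essentiality", "flags")
  if (!all(need %in% names(d))) {
    stop("canonical TSV must have columns: ", paste(need, collapse = ", "))
  }
  d$flags[is.na(d$flags)] <- ""
  lus <- d[d$feature == "lu", c("lu_id", "start", "end")]
  gd <- d[d$feature == "gene", ]
  genes <- data.frame(id = gd$gene_id, start = gd$start, end = gd$end,
                      strand = gd$strand, essentiality = gd$essentiality,
                      conditional = vapply(gd$flags, .cond_from_flags, ""),
                      replaced = grepl("replaced_by_reporter", gd$flags),
                      stringsAsFactors = FALSE)
  cen <- d[d$feature == "centromere", ]
  rep_row <- d[d$feature == "reporter", ]
  list(lus = lus, genes = genes,
       centromere = if (nrow(cen)) c(cen$start[1L], cen$end[1L]) else NULL,
       ura3_lu = if (nrow(rep_row)) rep_row$lu_id[1L] else NULL)
}

.cond_from_flags <- function(flags) {
  f <- strsplit(flags, ";", fixed = TRUE)[[1L]]
  paste(f[f != "" & f != "replaced_by_reporter"], collapse = ";")
}

.read_annot_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  to0 <- function(x) {
    data.frame(start = GenomicRanges::start(x) - 1L,
               end = GenomicRanges::end(x))
  }
  lu <- gr[typ == "loxPsym_unit"]
  lus <- cbind(data.frame(lu_id = lu$ID, stringsAsFactors = FALSE), to0(lu))
  gg <- gr[typ == "gene"]
  cond <- if (!is.null(gg$conditional)) {
    ifelse(is.na(gg$conditional), "", as.character(gg$conditional))
  } else rep("", length(gg))
  repl <- if (!is.null(gg$replaced)) {
    !is.na(gg$replaced) & gg$replaced == "true"
  } else rep(FALSE, length(gg))
  genes <- cbind(data.frame(id = gg$ID,
                            strand = as.character(GenomicRanges::strand(gg)),
                            essentiality = as.character(gg$essentiality),
                            conditional = cond, replaced = repl,
                            stringsAsFactors = FALSE), to0(gg))
  cen <- gr[typ == "centromere"]
  rep_f <- gr[typ == "reporter"]
  list(lus = lus, genes = genes,
       centromere = if (length(cen)) unlist(to0(cen)[1L, ], use.names = FALSE) else NULL,
       ura3_lu = if (length(rep_f)) as.character(rep_f$lu_id[1L]) else NULL)
}

#' Write a synthetic chromosome annotation
#'
#' @param chrom a `synthetic_chromosome`.
#' @param path output file.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(chrom, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  lt <- lu_table(chrom)
  g <- gene_table(chrom)
  cen <- NULL
  if (!is.null(chrom$centromere)) {
    cen_lu <- lt[lt$lu_id == chrom$centromere$lu_id, ]
    cen <- c(cen_lu$start + chrom$centromere$rel_start,
             cen_lu$start + chrom$centromere$rel_end)
  }
  if (format == "tsv") {
    flags <- ifelse(g$conditional == "", "", g$conditional)
    flags <- ifelse(g$replaced, paste0(flags, ifelse(flags == "", "", ";"),
                                       "replaced_by_reporter"), flags)
    rows <- rbind(
      data.frame(feature = "lu", lu_id = lt$lu_id, start = lt$start,
                 end = lt$end, gene_id = ".", strand = ".",
                 essentiality = ".", flags = "", stringsAsFactors = FALSE),
      data.frame(feature = "gene", lu_id = g$lu_id, start = g$start,
                 end = g$end, gene_id = g$id, strand = g$strand,
                 essentiality = g$essentiality, flags = flags,
                 stringsAsFactors = FALSE))
    if (!is.null(cen)) {
      rows <- rbind(rows,
        data.frame(feature = "centromere", lu_id = chrom$centromere$lu_id,
                   start = cen[1L], end = cen[2L], gene_id = ".", strand = ".",
                   essentiality = ".", flags = "", stringsAsFactors = FALSE))
    }
    if (!is.null(chrom$markers$URA3)) {
      ulu <- lt[lt$lu_id == chrom$markers$URA3, ]
      rows <- rbind(rows, data.frame(feature = "reporter", lu_id = ulu$lu_id,
                                     start = ulu$start, end = ulu$end,
                                     gene_id = "URA3", strand = ".",
                                     essentiality = ".", flags = "",
                                     stringsAsFactors = FALSE))
    }
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  st <- site_table(chrom)
  mk <- function(start0, end0, type, id = NA, extra = list()) {
    r <- GenomicRanges::GRanges(chrom$name,
                                IRanges::IRanges(start0 + 1L, end0),
                                strand = "*")
    r$type <- type
    r$ID <- id
    for (nm in names(extra)) S4Vectors::mcols(r)[[nm]] <- extra[[nm]]
    r
  }
  parts <- list(
    mk(lt$start, lt$end, "loxPsym_unit", lt$lu_id),
    mk(st$position, st$position + chrom$loxpsym_bp, "loxPsym_site",
       paste0("loxPsym_", st$index)))
  if (!is.null(cen)) parts <- c(parts, list(mk(cen[1L], cen[2L], "centromere", "CEN")))
  g2 <- mk(g$start, g$end, "gene", g$id,
           list(essentiality = g$essentiality,
                conditional = ifelse(g$conditional == "", NA, g$conditional),
                replaced = ifelse(g$replaced, "true", NA)))
  GenomicRanges::strand(g2) <- g$strand
  parts <- c(parts, list(g2))
  if (!is.null(chrom$markers$URA3)) {
    ulu <- lt[lt$lu_id == chrom$markers$URA3, ]
    rep_f <- mk(ulu$start, ulu$end, "reporter", "URA3",
                list(lu_id = ulu$lu_id))
    parts <- c(parts, list(rep_f))
  }
  all <- suppressWarnings(do.call(c, parts))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Full arm sequence including loxPsym 34-mers
#'
#' @param chrom a `synthetic_chromosome` with per-LU sequences.
#' @return a `Biostrings::DNAString`.
#' @export
chromosome_sequence <- function(chrom) {
  if (is.null(chrom$lu_seqs)) stop("chromosome carries no sequence")
  body <- paste0(vapply(chrom$lus$lu_id,
                        function(id) paste0(chrom$lu_seqs[[id]], LOXPSYM_SEQ), ""),
                 collapse = "")
  Biostrings::DNAString(paste0(LOXPSYM_SEQ, body))
}

#' Write the arm sequence as FASTA
#' @param chrom a `synthetic_chromosome` with sequence.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(chrom, path) {
  seq <- Biostrings::DNAStringSet(chromosome_sequence(chrom))
  names(seq) <- chrom$name
  Biostrings::writeXStringSet(seq, path, width = 80L)
  invisible(path)
}
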