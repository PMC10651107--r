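#' Construct a genome annotation
#'
#' A genome annotation is the package's central gene container: one interval
#' per gene, 0-based half-open coordinates (BED convention), with strand.
#' The transcription start site (TSS) of a `+` strand gene is `start`; for a
#' `-` strand gene it is `end - 1` (the biological 5' end). The transcription
#' end site (TES) is the opposite extremity.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`. Coordinates 0-based half-open; `strand` one of `"+"`, `"-"`.
#' @param chrom_sizes optional named numeric vector of chromosome lengths in
#'   bp; when present every gene must fit inside its chromosome.
#' @return A `genome_annotation` object (a data.frame with the columns above
#'   and a `chrom_sizes` attribute).
#' @examples
#' ann <- genome_annotation(data.frame(
#'   gene_id = "g1", chrom = "chr2L", start = 100, end = 200, strand = "+"))
#' gene_tss(ann)
#' @export
genome_annotation <- function(genes, chrom_sizes = NULL) {
  required <- c("gene_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes <- as.data.frame(genes)[, required, drop = FALSE]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$strand <- as.character(genes$strand)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  if (nrow(genes) > 0L) {
    if (anyDuplicated(genes$gene_id)) {
      stop("duplicate gene_id: ",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
    }
    if (any(!genes$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
    if (any(genes$start >= genes$end)) {
      bad <- genes$gene_id[genes$start >= genes$end]
      stop("start >= end for gene(s): ", paste(bad, collapse = ", "))
    }
    if (any(genes$start < 0)) stop("negative start coordinate")
  }
  if (!is.null(chrom_sizes)) {
    if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
    unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(unknown) > 0L) {
      stop("genes on chromosome(s) absent from chrom_sizes: ",
           paste(unknown, collapse = ", "))
    }
    over <- genes$end > chrom_sizes[genes$chrom]
    if (any(over)) {
      stop("gene(s) extend past chromosome end: ",
           paste(genes$gene_id[over], collapse = ", "))
    }
  }
  rownames(genes) <- NULL
  structure(genes, chrom_sizes = chrom_sizes,
            class = c("genome_annotation", "data.frame"))
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d gene(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Transcription start / end sites of an annotation
#'
#' Strand-aware anchors as 0-based positions: the TSS is the 5' base of the
#' gene in transcription orientation (`start` on `+`, `end - 1` on `-`), the
#' TES is the 3' base.
#'
#' @param annotation a [genome_annotation()].
#' @return Named numeric vector of positions (names are `gene_id`s).
#' @export
gene_tss <- function(annotation) {
  stats::setNames(ifelse(annotation$strand == "+", annotation$start,
                         annotation$end - 1), annotation$gene_id)
}

#' @rdname gene_tss
#' @export
gene_tes <- function(annotation) {
  stats::setNames(ifelse(annotation$strand == "+", annotation$end - 1,
                         annotation$start), annotation$gene_id)
}

## quick structural scan so parse errors can name the offending line
.scan_tab_file <- function(path, min_fields, skip_prefixes = c("#", "track", "browser")) {
  lines <- readLines(path, warn = FALSE)
  keep <- rep(TRUE, length(lines))
  for (p in skip_prefixes) keep <- keep & !startsWith(trimws(lines), p)
  keep <- keep & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(list(lines = character(0), line_no = integer(0)))
  nf <- lengths(strsplit(lines[idx], "\t", fixed = TRUE))
  bad <- which(nf < min_fields)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: expected >= %d tab-separated fields, found %d",
                 idx[bad[1]], basename(path), min_fields, nf[bad[1]]))
  }
  list(lines = lines[idx], line_no = idx)
}

#' Read gene models from a GTF file
#'
#' Rows whose feature (column 3) matches `feature` are grouped by the value
#' of `id_attribute`; each gene spans the minimum start to maximum end of its
#' rows. GTF 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention (`start := gtf_start - 1`).
#'
#' @param path GTF file path.
#' @param feature feature type to keep (column 3), default `"gene"`.
#' @param id_attribute attribute key carrying the gene identifier.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path, feature = "gene", id_attribute = "gene_id",
                     chrom_sizes = NULL) {
  scan <- .scan_tab_file(path, min_fields = 9L)
  if (length(scan$lines) == 0L) return(genome_annotation(
    data.frame(gene_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), strand = character(0)),
    chrom_sizes))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF ", basename(path), ": ",
                             conditionMessage(e)))
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) &
             as.character(S4Vectors::mcols(gr)$type) == feature]
  if (length(gr) == 0L) {
    stop("no '", feature, "' rows in ", basename(path))
  }
  ids <- S4Vectors::mcols(gr)[[id_attribute]]
  if (is.null(ids) || anyNA(ids)) {
    stop("feature rows missing attribute '", id_attribute, "' in ", basename(path))
  }
  df <- data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # to 0-based
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (any(!df$strand %in% c("+", "-"))) {
    stop("gene rows with missing/undefined strand in ", basename(path))
  }
  agg_start <- tapply(df$start, df$gene_id, min)
  agg_end <- tapply(df$end, df$gene_id, max)
  first <- df[!duplicated(df$gene_id), ]
  conflict <- tapply(seq_len(nrow(df)), df$gene_id, function(i) {
    length(unique(df$chrom[i])) > 1L || length(unique(df$strand[i])) > 1L
  })
  if (any(conflict)) {
    stop("duplicate gene_id with conflicting chrom/strand: ",
         paste(names(conflict)[conflict], collapse = ", "))
  }
  out <- data.frame(
    gene_id = first$gene_id,
    chrom = first$chrom,
    start = as.numeric(agg_start[first$gene_id]),
    end = as.numeric(agg_end[first$gene_id]),
    strand = first$strand,
    stringsAsFactors = FALSE)
  genome_annotation(out, chrom_sizes)
}

#' Read / write gene annotations as BED6
#'
#' BED6 is 0-based half-open, matching the internal convention, so the
#' round trip `read_bed(write_bed(x))` is the identity on coordinates, names
#' and strands.
#'
#' @param path BED6 file path.
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return `read_bed` returns a [genome_annotation()]; `write_bed` invisibly
#'   returns `path`.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  scan <- .scan_tab_file(path, min_fields = 6L)
  if (length(scan$lines) == 0L) {
    return(genome_annotation(
      data.frame(gene_id = character(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), strand = character(0)),
      chrom_sizes))
  }
  fields <- strsplit(scan$lines, "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(fields, `[[`, "", 1L),
    start = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L))),
    end = suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L))),
    gene_id = vapply(fields, `[[`, "", 4L),
    strand = vapply(fields, `[[`, "", 6L),
    stringsAsFactors = FALSE)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: non-numeric coordinates",
                 scan$line_no[bad[1]], basename(path)))
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0L) {
    stop(sprintf("line %d in %s: start >= end", scan$line_no[bad[1]],
                 basename(path)))
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0L) {
    stop(sprintf("line %d in %s: missing or invalid strand column",
                 scan$line_no[bad[1]], basename(path)))
  }
  genome_annotation(df[, c("gene_id", "chrom", "start", "end", "strand")],
                    chrom_sizes)
}

#' @rdname read_bed
#' @param annotation a [genome_annotation()] to write.
#' @export
write_bed <- function(annotation, path) {
  df <- data.frame(annotation$chrom,
                   format(annotation$start, scientific = FALSE, trim = TRUE),
                   format(annotation$end, scientific = FALSE, trim = TRUE),
                   annotation$gene_id, 0L, annotation$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
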