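#' Construct a genome annotation
#'
#' The annotation is the package's central gene model: one record per gene
#' with strand-aware TSS, a gene class, a transcript length (used by the
#' expression detection filter) and, for intron-hosted snoRNAs, a link to the
#' host gene that carries them. Coordinates are 0-based half-open throughout
#' the package; GTF input/output converts at the boundary.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand` (`"+"`/`"-"`), `gene_class` (one of
#'   `protein_coding`, `snoRNA`, `uhg`, `tRNA`, `other`),
#'   `transcript_length` (nt), and optionally `host_gene_id` and `category`.
#' @param chrom_sizes Named integer vector of chromosome lengths (nt).
#' @return An object of class `genome_annotation`: a list with elements
#'   `genes` (validated data.frame) and `chrom_sizes`.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  .stopifnot_cols(genes, c("gene_id", "chrom", "start", "end", "strand",
                           "gene_class", "transcript_length"),
                  "annotation 'genes'")
  if (!"host_gene_id" %in% names(genes)) genes$host_gene_id <- NA_character_
  if (!"category" %in% names(genes)) genes$category <- NA_character_
  genes$chrom <- as.character(genes$chrom)
  genes$gene_id <- as.character(genes$gene_id)
  genes$host_gene_id <- as.character(genes$host_gene_id)
  genes$category <- as.character(genes$category)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$transcript_length <- as.integer(genes$transcript_length)
  rownames(genes) <- NULL

  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) {
    bad <- genes$gene_id[genes$start >= genes$end]
    stop("gene interval(s) with start >= end: ", paste(bad, collapse = ", "))
  }
  if (any(genes$transcript_length < 1L)) {
    stop("transcript_length must be >= 1")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == "")) {
    stop("chrom_sizes must be a named vector")
  }
  unknown <- setdiff(genes$chrom, names(chrom_sizes))
  if (length(unknown)) {
    stop("gene(s) on chromosome(s) absent from chrom_sizes: ",
         paste(unknown, collapse = ", "))
  }
  sizes <- chrom_sizes[genes$chrom]
  if (any(genes$start < 0L) || any(genes$end > sizes)) {
    stop("gene interval(s) extend outside chrom_sizes")
  }
  linked <- !is.na(genes$host_gene_id)
  if (any(linked)) {
    host_idx <- match(genes$host_gene_id[linked], genes$gene_id)
    if (anyNA(host_idx)) {
      stop("host_gene_id refers to unknown gene(s): ",
           paste(unique(genes$host_gene_id[linked][is.na(host_idx)]),
                 collapse = ", "))
    }
    self <- genes$host_gene_id[linked] == genes$gene_id[linked]
    if (any(self)) stop("host_gene_id must differ from gene_id")
    contained <- genes$chrom[linked] == genes$chrom[host_idx] &
      genes$start[linked] >= genes$start[host_idx] &
      genes$end[linked] <= genes$end[host_idx]
    if (!all(contained)) {
      stop("host gene interval must contain the linked snoRNA interval: ",
           paste(genes$gene_id[linked][!contained], collapse = ", "))
    }
  }
  structure(list(genes = genes,
                 chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes))),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes on %d chromosome(s)\n",
              nrow(x$genes), length(x$chrom_sizes)))
  print(table(x$genes$gene_class))
  invisible(x)
}

#' Strand-aware transcription start sites
#'
#' @param ann A `genome_annotation`.
#' @return Integer vector of TSS positions (0-based), named by gene_id.
#'   The TSS is `start` for `+` genes and `end - 1` for `-` genes.
#' @export
gene_tss <- function(ann) {
  g <- ann$genes
  stats::setNames(ifelse(g$strand == "+", g$start, g$end - 1L), g$gene_id)
}

#' Read a genome annotation from GTF
#'
#' GTF coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention. Gene class, transcript length and functional
#' category are read from the `gene_class`, `transcript_length` and
#' `category` attributes when present; genes without a class default to
#' `"other"`, genes without a transcript length default to their interval
#' width. Intronic snoRNA to host-gene links can be given either as a
#' `host_gene_id` attribute or in a separate two-column TSV.
#'
#' @param path GTF file; only rows with feature type `gene` are used.
#' @param host_links Optional TSV with columns `sno_gene_id`,
#'   `host_gene_id`.
#' @param chrom_sizes Optional named vector; defaults to the maximal gene
#'   end per chromosome.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(path, host_links = NULL, chrom_sizes = NULL) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    stop(sprintf("malformed GTF line %d in '%s': expected 9 tab-separated fields",
                 which(body)[which(nfield != 9L)[1]], path))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "gene"]
  m <- S4Vectors::mcols(gr)
  genes <- data.frame(
    gene_id = as.character(m$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes$gene_class <- if ("gene_class" %in% names(m)) {
    ifelse(is.na(m$gene_class), "other", as.character(m$gene_class))
  } else "other"
  genes$transcript_length <- if ("transcript_length" %in% names(m)) {
    tl <- suppressWarnings(as.integer(m$transcript_length))
    ifelse(is.na(tl), genes$end - genes$start, tl)
  } else genes$end - genes$start
  genes$host_gene_id <- if ("host_gene_id" %in% names(m)) {
    as.character(m$host_gene_id)
  } else NA_character_
  genes$category <- if ("category" %in% names(m)) {
    as.character(m$category)
  } else NA_character_

  if (!is.null(host_links)) {
    links <- if (is.character(host_links) && length(host_links) == 1L) {
      utils::read.delim(host_links, stringsAsFactors = FALSE)
    } else as.data.frame(host_links)
    .stopifnot_cols(links, c("sno_gene_id", "host_gene_id"), "host_links")
    idx <- match(links$sno_gene_id, genes$gene_id)
    if (anyNA(idx)) {
      stop("host link names unknown sno gene(s): ",
           paste(links$sno_gene_id[is.na(idx)], collapse = ", "))
    }
    if (!all(links$host_gene_id %in% genes$gene_id)) {
      stop("host link names unknown host gene(s): ",
           paste(setdiff(links$host_gene_id, genes$gene_id), collapse = ", "))
    }
    genes$host_gene_id[idx] <- links$host_gene_id
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
    chrom_sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  }
  genome_annotation(genes, chrom_sizes)
}

#' Write a genome annotation to GTF (plus optional host-link TSV)
#'
#' @param ann A `genome_annotation`.
#' @param path Output GTF path (1-based inclusive coordinates).
#' @param host_links_path Optional path for the snoRNA/host link TSV.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, host_links_path = NULL) {
  g <- ann$genes
  attr_of <- function(i) {
    parts <- c(
      sprintf('gene_id "%s"', g$gene_id[i]),
      sprintf('gene_class "%s"', g$gene_class[i]),
      sprintf('transcript_length "%d"', g$transcript_length[i])
    )
    if (!is.na(g$host_gene_id[i])) {
      parts <- c(parts, sprintf('host_gene_id "%s"', g$host_gene_id[i]))
    }
    if (!is.na(g$category[i])) {
      parts <- c(parts, sprintf('category "%s"', g$category[i]))
    }
    paste0(paste(parts, collapse = "; "), ";")
  }
  lines <- vapply(seq_len(nrow(g)), function(i) {
    paste(g$chrom[i], "dmycTargets", "gene", g$start[i] + 1L, g$end[i], ".",
          g$strand[i], ".", attr_of(i), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  if (!is.null(host_links_path)) {
    linked <- !is.na(g$host_gene_id)
    utils::write.table(
      data.frame(sno_gene_id = g$gene_id[linked],
                 host_gene_id = g$host_gene_id[linked]),
      host_links_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Closest TSS for each peak or site
#'
#' For every query interval, finds the gene(s) whose TSS is nearest. The
#' distance is 0 when a TSS lies inside the half-open interval, otherwise the
#' gap in nt between the TSS and the nearest interval edge. All genes tied at
#' the minimal distance are returned. Optionally the distance is measured
#' from the peak summit instead of the interval.
#'
#' @param peaks data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and, when `from = "summit"`, `summit`.
#' @param ann A `genome_annotation`.
#' @param from `"edge"` (default, matches the behaviour of bedtools
#'   `closestBed`) or `"summit"`.
#' @return data.frame with columns `peak` (row index into `peaks`),
#'   `gene_id` and `distance` (nt, unsigned). Peaks on chromosomes with no
#'   annotated gene are reported with `gene_id = NA` and `distance = NA`,
#'   never dropped.
#' @export
closest_tss <- function(peaks, ann, from = c("edge", "summit")) {
  from <- match.arg(from)
  .stopifnot_cols(peaks, c("chrom", "start", "end"), "'peaks'")
  if (from == "summit") .stopifnot_cols(peaks, "summit", "'peaks'")
  g <- ann$genes
  tss <- gene_tss(ann)
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    on_chr <- which(g$chrom == peaks$chrom[i])
    if (!length(on_chr)) {
      out[[i]] <- data.frame(peak = i, gene_id = NA_character_,
                             distance = NA_integer_)
      next
    }
    t <- tss[on_chr]
    d <- if (from == "edge") {
      pmax(peaks$start[i] - t, t - peaks$end[i], 0L)
    } else {
      abs(t - peaks$summit[i])
    }
    dmin <- min(d)
    hit <- on_chr[d == dmin]
    out[[i]] <- data.frame(peak = i, gene_id = g$gene_id[hit],
                           distance = as.integer(dmin))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove reads perfectly matching rRNA references
#'
#' A read is discarded iff it occurs as an exact substring of any rRNA
#' reference sequence or of its reverse complement; a single mismatch
#' retains the read. Survivor order is preserved.
#'
#' @param reads Character vector of read sequences (alphabet A,C,G,T,N).
#' @param rrna_refs Character vector of rRNA reference sequences. Empty
#'   list: input returned unchanged.
#' @return Character vector of retained reads.
#' @export
remove_rrna_reads <- function(reads, rrna_refs) {
  if (length(rrna_refs) == 0L) return(reads)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rrna_refs)))
  targets <- c(rrna_refs, rc)
  keep <- vapply(reads, function(r) {
    !any(vapply(targets, function(ref) {
      grepl(r, ref, fixed = TRUE)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  reads[keep]
}
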