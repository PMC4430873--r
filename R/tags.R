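#' Construct a set of aligned ChIP tags
#'
#' A tag set holds the 5' alignment positions of a ChIP experiment under one
#' condition of the four-condition design: specific antibody vs non-immune
#' IgG, in naive vs Myc-depleted cells.
#'
#' @param tags data.frame with columns `chrom`, `pos` (0-based 5' position)
#'   and `strand`.
#' @param condition One of `specific_naive`, `specific_depleted`,
#'   `igg_naive`, `igg_depleted`.
#' @param chrom_sizes Optional named vector used to validate positions.
#' @return Object of class `tag_set` (a data.frame with a `condition`
#'   attribute).
#' @export
tag_set <- function(tags,
                    condition = c("specific_naive", "specific_depleted",
                                  "igg_naive", "igg_depleted"),
                    chrom_sizes = NULL) {
  condition <- match.arg(condition)
  .stopifnot_cols(tags, c("chrom", "pos", "strand"), "'tags'")
  tags <- data.frame(chrom = as.character(tags$chrom),
                     pos = as.integer(tags$pos),
                     strand = as.character(tags$strand),
                     stringsAsFactors = FALSE)
  if (!is.null(chrom_sizes)) {
    sz <- chrom_sizes[tags$chrom]
    if (anyNA(sz) || any(tags$pos < 0L) || any(tags$pos >= sz)) {
      stop("tag position(s) outside chrom_sizes")
    }
  }
  structure(tags, class = c("tag_set", "data.frame"), condition = condition)
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("tag_set [%s]: %d tags on %d chromosome(s)\n",
              attr(x, "condition"), nrow(x), length(unique(x$chrom))))
  invisible(x)
}

#' Subsample a tag set to a fixed depth
#'
#' Uniform sampling without replacement so that all conditions can be
#' compared at the same sequencing depth (the study design compares
#' conditions at one common number of uniquely aligned reads).
#'
#' @param tags A `tag_set`.
#' @param k Target number of tags; must not exceed the tag count.
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A `tag_set` with exactly `k` tags, in genomic input order.
#' @export
subsample_tags <- function(tags, k, seed) {
  n <- nrow(tags)
  if (k > n) stop(sprintf("cannot subsample %d tags from %d", k, n))
  idx <- sort(with_seed(seed, sample.int(n, k)))
  out <- tags[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("tag_set", "data.frame"),
            condition = attr(tags, "condition"))
}

#' Read/write tag sets as BED6 with 1-nt intervals at 5' ends
#'
#' @param tags A `tag_set`.
#' @param path BED file path.
#' @return `write_tags`: `path` invisibly. `read_tags`: a `tag_set`.
#' @export
write_tags <- function(tags, path) {
  utils::write.table(
    data.frame(tags$chrom, tags$pos, tags$pos + 1L,
               attr(tags, "condition"), 0L, tags$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tags
#' @param condition Condition label for the returned set.
#' @export
read_tags <- function(path, condition) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  tag_set(data.frame(chrom = bed[[1]], pos = bed[[2]], strand = bed[[6]]),
          condition = condition)
}

# Tag 5' position counts inside half-open intervals, per chromosome.
.count_tags <- function(tags, chrom, start0, end0) {
  n <- integer(length(start0))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    pos <- sort(tags$pos[tags$chrom == ch])
    n[sel] <- .count_in_intervals(pos, start0[sel], end0[sel])
  }
  n
}
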