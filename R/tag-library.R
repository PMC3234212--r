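#' Tag library container
#'
#' A tag library is the multiset of 5'-end positions of uniquely mapped
#' sequencing reads, plus library metadata. `total_mapped` is the
#' depth-normalization denominator; all downstream densities are reported
#' per `target` (default 1e7) mapped tags.
#'
#' @param tags data.frame with columns `chrom`, `pos` (0-based 5'-end
#'   coordinate) and `strand`; extra columns (e.g. simulator-provided 3'-end
#'   positions) are carried along.
#' @param read_length Read length in bp.
#' @param fragment_length Estimated ChIP fragment length in bp (`NA` for
#'   assays where tags are used unshifted: GRO-Seq, RNA-Seq, CAGE).
#' @param stranded Whether strand is biologically meaningful for counting.
#' @param total_mapped Total uniquely mapped tags; defaults to `nrow(tags)`.
#' @param shifted Internal flag: tags already shifted by half a fragment.
#' @return A `TagLibrary` object.
#' @export
tag_library <- function(tags, read_length, fragment_length = NA_integer_,
                        stranded = TRUE, total_mapped = nrow(tags),
                        shifted = FALSE) {
  tags <- as.data.frame(tags)
  if (!all(c("chrom", "pos", "strand") %in% names(tags)))
    stop("tags must have columns chrom, pos, strand")
  if (nrow(tags) > 0L) {
    if (any(tags$pos < 0L)) stop("tag positions must be >= 0")
    if (!all(tags$strand %in% c("+", "-"))) stop("tag strand must be + or -")
  }
  if (!is.na(read_length) && read_length <= 0L) stop("read_length must be positive")
  structure(list(tags = tags, read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 stranded = isTRUE(stranded),
                 total_mapped = as.numeric(total_mapped),
                 shifted = isTRUE(shifted)),
            class = "TagLibrary")
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf(
    "TagLibrary: %d tags (%s mapped), read length %s bp, fragment %s bp, %s%s\n",
    nrow(x$tags), format(x$total_mapped, big.mark = ","),
    ifelse(is.na(x$read_length), "?", x$read_length),
    ifelse(is.na(x$fragment_length), "-", x$fragment_length),
    if (x$stranded) "stranded" else "unstranded",
    if (x$shifted) ", shifted" else ""))
  invisible(x)
}

#' Read a tag library from BED6
#'
#' One BED record per uniquely mapped read. The tag position is the read's
#' 5' end: `start` for plus-strand records, `end - 1` for minus-strand
#' records. Malformed lines are rejected with their line numbers.
#'
#' @param path BED file with at least 6 columns.
#' @param fragment_length Optional ChIP fragment-length estimate to attach.
#' @param stranded Whether the library should be treated as stranded.
#' @return A [tag_library()].
#' @export
read_tag_bed <- function(path, fragment_length = NA_integer_, stranded = TRUE) {
  if (file.size(path) == 0)
    b <- data.table()
  else
    b <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
               colClasses = "character")
  if (nrow(b) == 0L)
    return(tag_library(data.frame(chrom = character(0), pos = integer(0),
                                  strand = character(0)),
                       read_length = NA_integer_,
                       fragment_length = fragment_length,
                       stranded = stranded, total_mapped = 0))
  if (ncol(b) < 6L)
    stop("BED tag file must have >= 6 columns (strand required), got ",
         ncol(b))
  start <- suppressWarnings(as.integer(as.character(b[[2]])))
  end <- suppressWarnings(as.integer(as.character(b[[3]])))
  strand <- as.character(b[[6]])
  bad <- which(is.na(start) | is.na(end) | end <= start |
                 !(strand %in% c("+", "-")))
  if (length(bad) > 0L)
    stop("malformed BED line(s): ",
         paste(head(bad, 20L), collapse = ", "),
         if (length(bad) > 20L) " ..." else "")
  pos <- ifelse(strand == "+", start, end - 1L)
  tag_library(data.frame(chrom = as.character(b[[1]]), pos = pos,
                         strand = strand),
              read_length = as.integer(stats::median(end - start)),
              fragment_length = fragment_length, stranded = stranded)
}

#' Write a tag library as BED6
#'
#' Records are `(chrom, start, start + read_length)` oriented so that the
#' stored 5'-end position round-trips through [read_tag_bed()].
#'
#' @param lib A [tag_library()].
#' @param path Output file.
#' @export
write_tag_bed <- function(lib, path) {
  t <- lib$tags
  L <- if (is.na(lib$read_length)) 1L else lib$read_length
  start <- ifelse(t$strand == "+", t$pos, t$pos - L + 1L)
  write.table(data.frame(t$chrom, start, start + L,
                         paste0("t", seq_len(nrow(t))), 1L, t$strand),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Depth-normalization weight of a library
#'
#' Every tag carries the same weight `target / total_mapped`, so the weighted
#' library mass is exactly `target` (default 1e7 mapped tags). Duplicate tags
#' at one position are all retained and all weighted.
#'
#' @param lib A [tag_library()].
#' @param target Normalization target in mapped tags.
#' @return Scalar per-tag weight.
#' @export
tag_weight <- function(lib, target = 1e7) {
  if (lib$total_mapped <= 0)
    stop("cannot normalize a library with total_mapped = 0")
  target / lib$total_mapped
}

#' Shift ChIP tags by half the fragment length
#'
#' Plus-strand tags move by `+floor(fragment_length / 2)`, minus-strand tags
#' by `-floor(fragment_length / 2)`, centering each tag on its sonicated
#' fragment. Applies to ChIP libraries only; GRO-Seq, RNA-Seq and CAGE tags
#' are counted at their raw 5' (or 3') ends because those positions are
#' themselves the signal.
#'
#' @param lib A [tag_library()] with `fragment_length` set.
#' @return The library with shifted positions and `shifted = TRUE`.
#' @export
shift_tags <- function(lib) {
  if (is.na(lib$fragment_length))
    stop("fragment_length is unset; required to shift a ChIP library")
  if (lib$shifted) stop("library is already shifted")
  half <- lib$fragment_length %/% 2L
  lib$tags$pos <- ifelse(lib$tags$strand == "+",
                         lib$tags$pos + half, lib$tags$pos - half)
  lib$shifted <- TRUE
  lib
}

# sorted position index per (chrom, strand-or-*) for O(log n) range counts
tag_index <- function(lib, stranded = FALSE) {
  t <- lib$tags
  key <- if (stranded) paste(t$chrom, t$strand) else t$chrom
  lapply(split(t$pos, key), sort)
}

# count positions in [lo, hi] inclusive within one sorted vector
count_sorted <- function(sorted_pos, lo, hi) {
  if (is.null(sorted_pos) || length(sorted_pos) == 0L || hi < lo) return(0L)
  findInterval(hi + 0.5, sorted_pos) - findInterval(lo - 0.5, sorted_pos)
}
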