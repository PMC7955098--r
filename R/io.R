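## Readers/writers for the plain-text formats the pipeline consumes:
## BED3/BED6 (tab-separated, no header), tagAlign (BED6 with 5'-end
## semantics), and two-column genome files ("chrom<TAB>length"). The parsers
## are deliberately strict: a malformed line fails with its line number.

split_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

parse_num <- function(x, what, i) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    abort(sprintf("line %d: %s is not numeric", i[which(is.na(v))[1]], what))
  }
  v
}

#' Read and write BED interval files
#'
#' `read_bed()` parses a 3+ column tab-separated BED file into a region
#' tibble; columns 4 and 5 populate `name` and `score` when present.
#' `write_bed()` writes the reverse mapping. Round trips are byte stable for
#' normalized sets.
#'
#' @param path File path.
#' @param genome Optional named vector of chromosome lengths to validate
#'   against and attach.
#' @return `read_bed()` returns a region tibble.
#' @export
read_bed <- function(path, genome = NULL) {
  fields <- split_tsv_lines(path)
  if (length(fields) == 0) {
    return(set_genome(tibble(chrom = character(), start = numeric(),
                             end = numeric()), genome))
  }
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    abort(sprintf("line %d: BED needs at least 3 columns",
                  which(ncol < 3)[1]))
  }
  i <- seq_along(fields)
  x <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = parse_num(vapply(fields, `[[`, "", 2), "start", i),
    end = parse_num(vapply(fields, `[[`, "", 3), "end", i)
  )
  if (all(ncol >= 4)) x$name <- vapply(fields, `[[`, "", 4)
  if (all(ncol >= 5)) {
    x$score <- parse_num(vapply(fields, `[[`, "", 5), "score", i)
  }
  bad <- which(x$end <= x$start)
  if (length(bad) > 0) {
    abort(sprintf("line %d: end must be greater than start", bad[1]))
  }
  validate_regions(x, genome = genome)
  set_genome(x, genome)
}

#' @rdname read_bed
#' @param x Region tibble.
#' @export
write_bed <- function(x, path) {
  validate_regions(x)
  cols <- list(x$chrom, format_coord(x$start), format_coord(x$end))
  has <- function(col) col %in% names(x)
  if (has("score")) {
    cols <- c(cols, list(if (has("name")) x$name else rep(".", nrow(x)),
                         as.character(x$score)))
  } else if (has("name")) {
    cols <- c(cols, list(x$name))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read and write genome files
#'
#' A genome file is two tab-separated columns, chromosome name and length.
#'
#' @param path File path.
#' @return `read_genome()` returns a named numeric vector of lengths.
#' @export
read_genome <- function(path) {
  fields <- split_tsv_lines(path)
  if (any(lengths(fields) < 2)) {
    abort(sprintf("line %d: genome file needs 2 columns",
                  which(lengths(fields) < 2)[1]))
  }
  len <- parse_num(vapply(fields, `[[`, "", 2), "length", seq_along(fields))
  setNames(len, vapply(fields, `[[`, "", 1))
}

#' @rdname read_genome
#' @param genome Named numeric vector of chromosome lengths.
#' @export
write_genome <- function(genome, path) {
  writeLines(paste(names(genome), format_coord(genome), sep = "\t"), path)
  invisible(path)
}
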