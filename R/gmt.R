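#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (the `description` field is kept
#'   as an attribute).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 1L) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1], ": fewer than 3 fields",
         call. = FALSE)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(names(sets)))
    stop("duplicated gene-set names in GMT", call. = FALSE)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

check_gene_sets <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names", call. = FALSE)
  empty <- which(lengths(sets) == 0)
  if (length(empty))
    stop("gene set '", names(sets)[empty[1]], "' is empty", call. = FALSE)
  invisible(sets)
}
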