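# Flat text I/O: TSV tables and a key/value config format mirroring the
# model_params field names (damage_bins as a comma-separated list).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Write a parameter configuration
#'
#' Flat `key<TAB>value` text, one field of [model_params()] per line;
#' `damage_bins` is comma-separated. Round-trips losslessly through
#' [read_config()].
#'
#' @param params A [model_params()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_params(params)
  fmt <- function(v) {
    if (is.logical(v)) return(as.character(v))
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = ",")
  }
  lines <- vapply(names(unclass(params)),
                  function(nm) paste(nm, fmt(params[[nm]]), sep = "\t"),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter configuration written by [write_config()]
#'
#' @param path Config file path.
#' @return A validated [model_params()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[[`, character(1), 1L)
  vals <- vapply(kv, `[[`, character(1), 2L)
  bad <- setdiff(keys, names(formals(model_params)))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  args <- lapply(seq_along(keys), function(i) {
    v <- vals[i]
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  names(args) <- keys
  do.call(model_params, args)
}

#' Write a population snapshot as TSV
#' @param pop A population snapshot data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(pop, path) write_tsv(pop, path)

#' Read a population snapshot written by [write_snapshot()]
#' @param path Snapshot file path.
#' @return A population snapshot data.frame.
#' @export
read_snapshot <- function(path) {
  pop <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  for (nm in setdiff(names(pop), c("viability_1", "viability_2")))
    pop[[nm]] <- as.numeric(pop[[nm]])
  pop$id <- as.integer(pop$id)
  pop$age <- as.integer(pop$age)
  pop
}
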