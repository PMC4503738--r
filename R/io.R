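#' Read a weighted edge list (TSV)
#'
#' The dialect is a header line `source	target	weight`, 0-based integer node
#' ids, one undirected edge per line with `source < target`. Lines starting
#' with `#` are ignored. Malformed rows, self-loops, duplicates and
#' non-positive weights are rejected with the offending line number.
#'
#' @param path File path.
#' @param n_nodes Number of nodes; default `max(id) + 1`.
#' @return A [weighted_network()].
#' @export
read_edges <- function(path, n_nodes = NULL) {
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- raw[keep]
  if (!length(lines)) stop("no content in ", path, call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(tolower(header[1:2]), c("source", "target")))
    stop("missing 'source\ttarget\tweight' header in ", path, call. = FALSE)
  body <- lines[-1]
  body_lineno <- lineno[-1]
  if (!length(body)) {
    if (is.null(n_nodes)) n_nodes <- 0L
    return(empty_network(max(1L, n_nodes)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed row at line ", body_lineno[bad[1]], " of ", path,
         call. = FALSE)
  src <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
  tgt <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  w <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(src) | is.na(tgt) | is.na(w))
  if (length(bad))
    stop("malformed row at line ", body_lineno[bad[1]], " of ", path,
         call. = FALSE)
  bad <- which(src == tgt)
  if (length(bad))
    stop("self-loop at line ", body_lineno[bad[1]], " of ", path,
         call. = FALSE)
  bad <- which(w <= 0)
  if (length(bad))
    stop("non-positive weight at line ", body_lineno[bad[1]], " of ", path,
         call. = FALSE)
  key <- paste(pmin(src, tgt), pmax(src, tgt))
  bad <- which(duplicated(key))
  if (length(bad))
    stop("duplicate edge at line ", body_lineno[bad[1]], " of ", path,
         call. = FALSE)
  if (is.null(n_nodes)) n_nodes <- max(src, tgt) + 1L
  weighted_network(data.frame(i = src + 1L, j = tgt + 1L, w = w), n_nodes)
}

#' Write a weighted edge list (TSV)
#'
#' Canonical form: header `source	target	weight`, 0-based ids,
#' `source < target`, rows sorted by `(source, target)`.
#'
#' @param net A [weighted_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  e <- net$edges
  lines <- c("source\ttarget\tweight",
             sprintf("%d\t%d\t%.15g", e$i - 1L, e$j - 1L, e$w))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat key = value configuration file
#'
#' TOML-style flat assignments, one per line, keys matching the
#' [model_params()] field names exactly. `#` comments and blank lines are
#' ignored; string values may be quoted.
#'
#' @param path File path.
#' @return Named list with numeric values coerced.
#' @export
read_config <- function(path) {
  raw <- readLines(path)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  out <- list()
  for (line in raw) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", line, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$|^\'|\'$', "", val)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Build `model_params` from a configuration list or file
#'
#' @param config Path to a config file or a named list as returned by
#'   [read_config()].
#' @param ... Overrides passed on to [model_params()].
#' @return A [model_params()] object.
#' @export
params_from_config <- function(config, ...) {
  if (is.character(config)) config <- read_config(config)
  over <- list(...)
  config[names(over)] <- over
  known <- c("n_nodes", "mechanism", "p_delta", "p_r", "w0", "delta",
             "p_nd", "p_ld", "aging_factor", "w_th", "steps", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(model_params, config)
}
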