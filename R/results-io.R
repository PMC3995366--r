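fmt_num <- function(x) sprintf("%.17g", x)

#' Write a run result to a plain-text file
#'
#' The file layout is fixed for reproducibility: `#`-prefixed header lines
#' (node count, threshold, connectivity, runs, seed, gamma, number of
#' unique sets), the deterministic greedy set flagged as `# greedy:`, then
#' one line per unique maximal independent set — members sorted by label,
#' whitespace-separated, lines ordered by decreasing set size then
#' lexicographically — and a closing `# sizes:` five-number summary block.
#' Each set appears exactly once however often the runs rediscovered it.
#'
#' @param result an `indep_run` object from [run_heuristic()].
#' @param path output path.
#' @param exact optional character vector: a maximum independent set from
#'   [maximum_independent_set()], recorded as an `# exact:` header line.
#' @param timestamp write a `# written:` line (set `FALSE` for
#'   byte-reproducible artifacts).
#' @param json also write a machine-readable companion with the same
#'   content to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @seealso [read_result_file()]
#' @export
write_result_file <- function(result, path, exact = NULL, timestamp = TRUE,
                              json = FALSE) {
  stopifnot(inherits(result, "indep_run"))
  if (!length(result$unique_sets)) {
    stop("empty result: nothing to write", call. = FALSE)
  }
  q <- size_quantiles(result)
  header <- c(
    "# maximal independent sets",
    if (timestamp) sprintf("# written: %s",
                           format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("# nodes: %d", result$n),
    sprintf("# threshold: %s", fmt_num(result$threshold)),
    sprintf("# connectivity: %s", fmt_num(result$connectivity)),
    sprintf("# runs: %d", result$runs),
    sprintf("# seed: %s",
            if (is.na(result$seed)) "NA" else as.character(result$seed)),
    sprintf("# gamma: %s", fmt_num(result$gamma)),
    sprintf("# unique_sets: %d", length(result$unique_sets)),
    sprintf("# greedy: %s", paste(result$greedy_set, collapse = " ")),
    if (!is.null(exact)) sprintf("# exact: %s", paste(exact, collapse = " "))
  )
  set_lines <- vapply(result$unique_sets, paste, character(1L),
                      collapse = " ")
  footer <- sprintf("# sizes: min %g | 25%% %g | median %g | 75%% %g | max %g",
                    q[1L], q[2L], q[3L], q[4L], q[5L])
  writeLines(c(header, set_lines, footer), path)
  if (isTRUE(json)) {
    jsonlite::write_json(
      list(nodes = result$n, threshold = result$threshold,
           connectivity = result$connectivity, runs = result$runs,
           seed = result$seed, gamma = result$gamma,
           greedy = result$greedy_set,
           exact = exact,
           unique_sets = result$unique_sets,
           size_quantiles = as.list(q)),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Read back a result file
#'
#' Parses a file written by [write_result_file()].
#'
#' @param path path to the result file.
#' @return A list with `sets` (list of character vectors), `greedy`,
#'   `exact` (`NULL` if absent), and the header fields `nodes`,
#'   `threshold`, `connectivity`, `runs`, `seed`, `gamma`.
#' @export
read_result_file <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("result file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path)
  grab <- function(key) {
    hit <- grep(sprintf("^# %s: ", key), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(sprintf("^# %s: ", key), "", hit[1L])
  }
  split_ws <- function(s) strsplit(trimws(s), "[ \t]+")[[1L]]
  set_lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  exact <- grab("exact")
  list(
    sets = lapply(set_lines, split_ws),
    greedy = split_ws(grab("greedy")),
    exact = if (is.null(exact)) NULL else split_ws(exact),
    nodes = as.integer(grab("nodes")),
    threshold = as.numeric(grab("threshold")),
    connectivity = as.numeric(grab("connectivity")),
    runs = as.integer(grab("runs")),
    seed = suppressWarnings(as.integer(grab("seed"))),
    gamma = as.numeric(grab("gamma"))
  )
}
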