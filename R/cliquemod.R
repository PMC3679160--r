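#' Enumerate functional modules as maximal cliques
#'
#' A functional module is a maximal clique of the network: every member pair
#' is linked (modularity Q = 1) and no outside protein is adjacent to all
#' members. Enumeration uses the pivoted Bron-Kerbosch algorithm; the result
#' is canonicalized so it is independent of node and edge input order.
#'
#' @param net An undirected simple igraph network.
#' @param min_size Smallest clique size to report (default 2).
#' @return A `data.frame` of class `functional_modules` with columns
#'   `module_id` (semicolon-joined sorted members), `size`, and a list-column
#'   `members`; rows sorted by descending size, then lexicographic
#'   `module_id`.
#' @export
enumerate_maximal_cliques <- function(net, min_size = 2L) {
  stopifnot(min_size >= 2L)
  if (igraph::vcount(net) == 0L) {
    return(new_functional_modules(list()))
  }
  if (igraph::any_multiple(net) || any(igraph::which_loop(net))) {
    stop("network must be simple (no loops or parallel edges)")
  }
  cl <- igraph::max_cliques(net, min = min_size)
  members <- lapply(cl, function(v) sort(igraph::V(net)$name[v]))
  new_functional_modules(members)
}

new_functional_modules <- function(members) {
  if (length(members) == 0L) {
    df <- data.frame(module_id = character(), size = integer(),
                     stringsAsFactors = FALSE)
    df$members <- list()
    class(df) <- c("functional_modules", "data.frame")
    return(df)
  }
  ids <- vapply(members, paste, "", collapse = ";")
  sizes <- lengths(members)
  o <- order(-sizes, ids)
  df <- data.frame(module_id = ids[o], size = as.integer(sizes[o]),
                   stringsAsFactors = FALSE)
  df$members <- members[o]
  class(df) <- c("functional_modules", "data.frame")
  df
}

#' Filter modules by size and summarize the input list
#'
#' The statistics (count, size range, mean size) describe the list *before*
#' filtering, so the reported numbers characterize the full enumeration.
#'
#' @param modules A `functional_modules` data frame.
#' @param min_size Minimum module size to retain (>= 2; default 4, the
#'   smallest size usually considered biologically meaningful).
#' @return List with `modules` (the filtered data frame, order preserved) and
#'   `stats`: `count`, `min_size`, `max_size`, `mean_size` (NA when the input
#'   is empty).
#' @export
size_filter_and_stats <- function(modules, min_size = 4L) {
  stopifnot(min_size >= 2L)
  n <- nrow(modules)
  stats <- if (n == 0L) {
    list(count = 0L, min_size = NA_integer_, max_size = NA_integer_,
         mean_size = NA_real_)
  } else {
    list(count = n, min_size = min(modules$size),
         max_size = max(modules$size),
         mean_size = round(mean(modules$size), 4L))
  }
  list(modules = modules[modules$size >= min_size, , drop = FALSE],
       stats = stats)
}

#' Write modules to TSV (module_id, size, semicolon-joined members)
#'
#' @param modules A `functional_modules` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, path) {
  df <- data.frame(module_id = modules$module_id, size = modules$size,
                   members = vapply(modules$members, paste, "",
                                    collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read modules written by [write_modules()]
#'
#' @param path Path to the modules TSV.
#' @return A `functional_modules` data frame.
#' @export
read_modules <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_functional_modules(strsplit(df$members, ";", fixed = TRUE))
}
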