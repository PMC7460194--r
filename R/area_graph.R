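#' Areal adjacency graphs
#'
#' An `area_graph` stores the contiguity structure of a set of areal units
#' (counties, districts, grid cells): for each area, the set of areas sharing a
#' boundary with it. It is the substrate of the intrinsic CAR prior, whose full
#' conditional for an area is centered on the mean of its neighbors with
#' variance inversely proportional to the neighbor count.
#'
#' Areas are canonically ordered by the sorted order of their identifiers; all
#' downstream panel and model indexing follows that order.
#'
#' @param area_ids character vector of unique area identifiers.
#' @param neighbors list (same length) of character vectors: the ids adjacent
#'   to each area. Must be symmetric and free of self-loops.
#' @return An object of class `area_graph` with elements `n` (area count),
#'   `ids`, `neighbors` (list of integer index vectors into the canonical
#'   order), `m` (integer neighbor counts) and `component` (integer
#'   connected-component labels).
#' @examples
#' g <- area_graph(c("a", "b", "c"), list("b", c("a", "c"), "b"))
#' g$m # 1 2 1
#' @export
area_graph <- function(area_ids, neighbors) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) stopf("duplicate area ids")
  if (length(neighbors) != length(area_ids)) {
    stopf("neighbors must have one entry per area")
  }
  ord <- order(area_ids)
  ids <- area_ids[ord]
  nb_chr <- neighbors[ord]
  idx <- lapply(nb_chr, function(v) {
    v <- as.character(v)
    j <- match(v, ids)
    if (anyNA(j)) stopf("unknown neighbor id(s): %s", paste(v[is.na(j)], collapse = ", "))
    sort(unique(j))
  })
  new_area_graph(ids, idx)
}

# internal constructor from integer-index neighbor lists (canonical order)
#' @noRd
new_area_graph <- function(ids, nb_idx, symmetrize = FALSE) {
  n <- length(ids)
  for (i in seq_len(n)) {
    if (i %in% nb_idx[[i]]) stopf("self-loop at area '%s'", ids[i])
  }
  # symmetry
  asym <- FALSE
  for (i in seq_len(n)) {
    for (j in nb_idx[[i]]) {
      if (!(i %in% nb_idx[[j]])) {
        if (!symmetrize) stopf("asymmetric adjacency: '%s' lists '%s' but not vice versa", ids[i], ids[j])
        nb_idx[[j]] <- sort(unique(c(nb_idx[[j]], i)))
        asym <- TRUE
      }
    }
  }
  if (asym) warnf("adjacency was asymmetric; symmetrized")
  g <- structure(
    list(
      n = n, ids = ids, neighbors = nb_idx,
      m = vapply(nb_idx, length, integer(1)),
      component = graph_components(nb_idx)
    ),
    class = "area_graph"
  )
  g
}

# BFS connected-component labels
#' @noRd
graph_components <- function(nb_idx) {
  n <- length(nb_idx)
  comp <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (w in nb_idx[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- lab
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' @export
print.area_graph <- function(x, ...) {
  cat(sprintf(
    "<area_graph> %d areas, %d edges, %d component(s), %d isolated\n",
    x$n, sum(x$m) %/% 2L, max(x$component), sum(x$m == 0L)
  ))
  invisible(x)
}

#' Rook-contiguity lattice graph
#'
#' Builds a `rows` x `cols` grid of areas in which each cell is adjacent to its
#' horizontal and vertical neighbors — a stand-in for a county contiguity map
#' with a known, regular structure.
#'
#' @param rows,cols positive integers.
#' @return An [area_graph] with `rows * cols` areas; ids are `g0001`, ... in
#'   row-major order.
#' @examples
#' make_lattice_graph(2, 2)$m # all 2
#' @export
make_lattice_graph <- function(rows, cols) {
  if (rows < 1 || cols < 1) stopf("rows and cols must be >= 1")
  n <- rows * cols
  ids <- sprintf("g%04d", seq_len(n))
  at <- function(r, c) (r - 1L) * cols + c
  nb <- vector("list", n)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      v <- integer(0)
      if (r > 1) v <- c(v, at(r - 1L, c))
      if (r < rows) v <- c(v, at(r + 1L, c))
      if (c > 1) v <- c(v, at(r, c - 1L))
      if (c < cols) v <- c(v, at(r, c + 1L))
      nb[[at(r, c)]] <- sort(v)
    }
  }
  new_area_graph(ids, nb)
}

#' Read a GAL spatial-weights file
#'
#' Parses the classic GAL dialect: a header line carrying the number of areas
#' (either `n` alone or the four-token `0 n shapefile var` form), then for each
#' area a line `id k` followed by a line with its `k` neighbor ids. Areas with
#' zero neighbors are kept as isolated nodes. Asymmetric listings are
#' symmetrized with a warning; neighbor ids that name no area are an error.
#'
#' @param path path to a GAL file.
#' @return An [area_graph].
#' @seealso [write_gal()]
#' @export
read_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("GAL parse error at line 1: empty file")
  head_tok <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  n_str <- if (length(head_tok) == 1L) head_tok[[1]] else if (head_tok[[1]] == "0") head_tok[[2]] else NA
  n <- suppressWarnings(as.integer(n_str))
  if (is.na(n) || n < 1) stopf("GAL parse error at line 1: malformed header '%s'", lines[[1]])
  ids <- character(n)
  raw_nb <- vector("list", n)
  ln <- 1L
  for (a in seq_len(n)) {
    ln <- ln + 1L
    if (ln > length(lines)) stopf("GAL parse error: file ends before area %d", a)
    tok <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
    if (length(tok) != 2L) stopf("GAL parse error at line %d: expected 'id count'", ln)
    ids[a] <- tok[[1]]
    k <- suppressWarnings(as.integer(tok[[2]]))
    if (is.na(k) || k < 0) stopf("GAL parse error at line %d: bad neighbor count", ln)
    if (k == 0L) {
      raw_nb[[a]] <- character(0)
    } else {
      ln <- ln + 1L
      if (ln > length(lines)) stopf("GAL parse error: missing neighbor line for area '%s'", ids[a])
      v <- strsplit(trimws(lines[[ln]]), "\\s+")[[1]]
      if (length(v) != k) stopf("GAL parse error at line %d: %d neighbors listed, %d declared", ln, length(v), k)
      raw_nb[[a]] <- v
    }
  }
  ord <- order(ids)
  sids <- ids[ord]
  if (anyDuplicated(sids)) stopf("GAL parse error: duplicate area id")
  nb_idx <- lapply(raw_nb[ord], function(v) {
    j <- match(v, sids)
    if (anyNA(j)) stopf("GAL parse error: dangling neighbor id(s): %s", paste(v[is.na(j)], collapse = ", "))
    sort(unique(j))
  })
  new_area_graph(sids, nb_idx, symmetrize = TRUE)
}

#' Write a GAL spatial-weights file
#'
#' @param graph an [area_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  out <- character(1L + 2L * graph$n)
  out[1] <- as.character(graph$n)
  k <- 1L
  for (i in seq_len(graph$n)) {
    k <- k + 1L
    out[k] <- paste(graph$ids[i], graph$m[i])
    if (graph$m[i] > 0L) {
      k <- k + 1L
      out[k] <- paste(graph$ids[graph$neighbors[[i]]], collapse = " ")
    }
  }
  writeLines(out[seq_len(k)], path)
  invisible(path)
}
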