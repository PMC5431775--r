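#' Write a network to disk
#'
#' Two lossless formats are supported:
#' \describe{
#'   \item{`"tsv"`}{a plain-text dialect with a node section
#'     (`node <id> <x> <y> <is_bridge>`) followed by an edge section
#'     (`edge <from> <to>`). Node ids are 0-based insertion order and
#'     coordinates are written at full double precision.}
#'   \item{`"graphml"`}{standard GraphML through igraph, with `x`, `y` and
#'     `is_bridge` vertex attributes.}
#' }
#'
#' @param net a `geomnet`, or an `igraph` graph (coordinates optional for
#'   the igraph case).
#' @param path output file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return the path, invisibly.
#' @seealso [read_network()]
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  g <- .as_graph(net)
  if (format == "graphml") {
    ok <- try(igraph::write_graph(g, path, format = "graphml"), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop(sprintf("failed to write '%s': %s", path, attr(ok, "condition")$message))
    return(invisible(path))
  }
  xa <- igraph::vertex_attr(g, "x")
  ya <- igraph::vertex_attr(g, "y")
  br <- igraph::vertex_attr(g, "is_bridge")
  nv <- igraph::vcount(g)
  if (is.null(xa)) xa <- rep(NA_real_, nv)
  if (is.null(ya)) ya <- rep(NA_real_, nv)
  if (is.null(br)) br <- rep(FALSE, nv)
  el <- igraph::as_edgelist(g, names = FALSE)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop(sprintf("cannot open '%s' for writing", path))
  on.exit(close(con))
  writeLines("# geogrow network v1", con)
  writeLines(sprintf("node\t%d\t%s\t%s\t%d",
                     seq_len(nv) - 1L,
                     formatC(xa, format = "g", digits = 17),
                     formatC(ya, format = "g", digits = 17),
                     as.integer(br)), con)
  if (nrow(el))
    writeLines(sprintf("edge\t%d\t%d", el[, 1L] - 1L, el[, 2L] - 1L), con)
  invisible(path)
}

#' Read a network from disk
#'
#' Reads the formats written by [write_network()]. For `"tsv"`, a plain
#' two- or three-column edge list (whitespace-separated integer pairs,
#' `#` comments allowed) is also accepted and yields a coordinate-free
#' graph; operations that need geometry will reject such graphs. Duplicate
#' edges are collapsed to a single edge with a warning; malformed lines
#' raise an error naming the line number.
#'
#' @param path input file path.
#' @param format `"tsv"` or `"graphml"`.
#' @return a `geomnet` when coordinates are present, otherwise an
#'   [igraph::igraph] graph.
#' @export
read_network <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(.graph_to_geomnet(g))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("file contains no records")
  toks <- strsplit(lines, "[\t ]+")

  if (any(vapply(toks, `[[`, character(1), 1L) == "node")) {
    node_rows <- vapply(toks, `[[`, character(1), 1L) == "node"
    edge_rows <- vapply(toks, `[[`, character(1), 1L) == "edge"
    bad <- which(!node_rows & !edge_rows)
    if (length(bad))
      stop(sprintf("malformed line %d: expected a 'node' or 'edge' record",
                   lineno[bad[1L]]))
    nt <- toks[node_rows]
    if (any(lengths(nt) != 5L))
      stop(sprintf("malformed node record at line %d",
                   lineno[node_rows][which(lengths(nt) != 5L)[1L]]))
    ids <- as.integer(vapply(nt, `[[`, character(1), 2L))
    xs <- as.numeric(vapply(nt, `[[`, character(1), 3L))
    ys <- as.numeric(vapply(nt, `[[`, character(1), 4L))
    brs <- as.integer(vapply(nt, `[[`, character(1), 5L)) != 0L
    if (anyNA(ids) || anyNA(brs))
      stop("malformed node record: non-numeric id or bridge flag")
    ord <- order(ids)
    xs <- xs[ord]; ys <- ys[ord]; brs <- brs[ord]
    et <- toks[edge_rows]
    if (any(lengths(et) != 3L))
      stop(sprintf("malformed edge record at line %d",
                   lineno[edge_rows][which(lengths(et) != 3L)[1L]]))
    ef <- as.integer(vapply(et, `[[`, character(1), 2L)) + 1L
    eto <- as.integer(vapply(et, `[[`, character(1), 3L)) + 1L
    if (anyNA(ef) || anyNA(eto)) stop("malformed edge record: non-integer id")
    el <- cbind(ef, eto)
    el <- .dedup_edges(el)
    return(geomnet(xs, ys, el, is_bridge = brs))
  }

  # plain edge list: two integer columns (extra columns ignored)
  if (any(lengths(toks) < 2L))
    stop(sprintf("malformed line %d: expected at least two columns",
                 lineno[which(lengths(toks) < 2L)[1L]]))
  a <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 1L)))
  b <- suppressWarnings(as.integer(vapply(toks, `[[`, character(1), 2L)))
  if (anyNA(a) || anyNA(b))
    stop(sprintf("malformed line %d: non-integer node id",
                 lineno[which(is.na(a) | is.na(b))[1L]]))
  off <- 1L - min(c(a, b))        # accept 0- or 1-based ids
  el <- .dedup_edges(cbind(a + off, b + off))
  g <- igraph::make_empty_graph(n = max(el), directed = FALSE)
  igraph::add_edges(g, as.vector(t(el)))
}

.dedup_edges <- function(el) {
  if (any(el[, 1L] == el[, 2L])) stop("self-loops are not allowed")
  key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate edge(s)", sum(dup)))
    el <- el[!dup, , drop = FALSE]
  }
  el
}

.graph_to_geomnet <- function(g) {
  xa <- igraph::vertex_attr(g, "x")
  ya <- igraph::vertex_attr(g, "y")
  if (is.null(xa) || is.null(ya)) return(g)
  br <- igraph::vertex_attr(g, "is_bridge")
  if (is.null(br)) br <- rep(FALSE, igraph::vcount(g))
  geomnet(xa, ya, igraph::as_edgelist(g, names = FALSE),
          is_bridge = as.logical(br))
}

#' Run manifest for a generated network
#'
#' Collects the configuration, seed, package version and derived counts of a
#' generation run, and asserts the structural identities
#' `|V| = N + B` and `|E| = sum_i min(i - 1, m) + B`.
#'
#' @param net a `geomnet` produced by [grow_network()].
#' @return a list suitable for JSON serialization.
#' @export
run_manifest <- function(net) {
  stopifnot(inherits(net, "geomnet"))
  cfg <- net$config
  if (is.null(cfg)) stop("network carries no generation config")
  nv <- length(net$x); ne <- nrow(net$edges); B <- net$n_bridge
  expect_edges <- sum(pmin(seq_len(cfg$N) - 1L, cfg$m)) + B
  if (nv != cfg$N + B || ne != expect_edges)
    stop("structural identities violated; the network was not produced by a clean run")
  list(config = cfg[c("N", "m", "R", "T")],
       seed = if (is.null(cfg$seed)) NA else cfg$seed,
       package_version = as.character(utils::packageVersion("geogrow")),
       nodes = nv, bridges = B, edges = ne)
}
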