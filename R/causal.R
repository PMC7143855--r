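#' @title Causal loop diagram analysis
#' @description Signed digraphs, elementary feedback-loop enumeration and
#'   polarity classification. A loop is reinforcing (positive) when it has an
#'   even number of negative edges and balancing (negative) otherwise.
#' @name causal_analysis
NULL

#' Construct a signed digraph
#'
#' @param edges Data frame with columns `from`, `to` (character) and `sign`
#'   (+1 or -1, or the characters `"+"` / `"-"`). Parallel edges between the
#'   same ordered pair are not allowed.
#' @return An object of class `signed_digraph` with components `nodes` (sorted
#'   character vector) and `edges` (data frame, deterministically ordered).
#' @export
signed_digraph <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "sign") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.character(edges$sign))
    edges$sign <- ifelse(edges$sign == "+", 1L,
                         ifelse(edges$sign == "-", -1L, NA_integer_))
  edges$sign <- as.integer(edges$sign)
  if (anyNA(edges$sign) || !all(edges$sign %in% c(-1L, 1L)))
    stop("edge signs must be +1 or -1 (or '+'/'-')", call. = FALSE)
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("duplicate edge(s): %s",
                 paste(gsub("\r", " -> ", unique(key[duplicated(key)])),
                       collapse = ", ")), call. = FALSE)
  edges <- edges[order(edges$from, edges$to, method = "radix"),
                 c("from", "to", "sign")]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(c(edges$from, edges$to)), method = "radix"),
                 edges = edges),
            class = "signed_digraph")
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("<signed_digraph> %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == 1L),
              sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Classify the polarity of a feedback loop
#'
#' @param loop_signs Non-empty vector of edge signs (+1/-1) around the loop.
#' @return `"positive"` (reinforcing; even number of negative edges) or
#'   `"negative"` (balancing; odd number).
#' @export
classify_polarity <- function(loop_signs) {
  if (length(loop_signs) == 0L)
    stop("loop_signs must be non-empty", call. = FALSE)
  loop_signs <- as.integer(loop_signs)
  if (!all(loop_signs %in% c(-1L, 1L)))
    stop("loop signs must be +1 or -1", call. = FALSE)
  if (sum(loop_signs == -1L) %% 2L == 0L) "positive" else "negative"
}

#' Enumerate elementary feedback loops
#'
#' Finds every elementary cycle exactly once by a depth-first search rooted at
#' each node in turn, restricted to nodes not lexicographically smaller than
#' the root, so each cycle is reported in its canonical rotation (starting at
#' its smallest node). The result is sorted lexicographically by node
#' sequence, which makes the enumeration deterministic.
#'
#' @param graph A [signed_digraph()].
#' @return A list of class `feedback_loops`; each element has `nodes` (the
#'   cycle in canonical rotation), `edge_signs` (sign of the edge leaving each
#'   node) and `polarity`.
#' @export
enumerate_loops <- function(graph) {
  stopifnot(inherits(graph, "signed_digraph"))
  e <- graph$edges
  adj <- split(e$to, factor(e$from, levels = graph$nodes))
  sign_of <- stats::setNames(e$sign, paste(e$from, e$to, sep = "\r"))
  cycles <- list()
  for (root in graph$nodes) {
    path <- character()
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      for (w in sort(adj[[v]], method = "radix")) {
        if (w == root) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (w > root && !(w %in% path)) {
          dfs(w)
        }
      }
      path <<- path[-length(path)]
    }
    dfs(root)
  }
  keys <- vapply(cycles, function(p) paste(p, collapse = "\001"), character(1))
  cycles <- cycles[order(keys, method = "radix")]
  loops <- lapply(cycles, function(p) {
    nxt <- c(p[-1L], p[1L])
    signs <- unname(sign_of[paste(p, nxt, sep = "\r")])
    structure(list(nodes = p, edge_signs = signs,
                   polarity = classify_polarity(signs)),
              class = "feedback_loop")
  })
  structure(loops, class = "feedback_loops")
}

#' @export
print.feedback_loops <- function(x, ...) {
  pol <- vapply(x, `[[`, character(1), "polarity")
  cat(sprintf("%d feedback loop(s): %d positive, %d negative\n",
              length(x), sum(pol == "positive"), sum(pol == "negative")))
  for (i in seq_along(x)) {
    l <- x[[i]]
    cat(sprintf("  (%d) [%s] %s\n", i, l$polarity,
                paste(c(l$nodes, l$nodes[1L]), collapse = " -> ")))
  }
  invisible(x)
}

#' Built-in causal loop diagram of the coal-mining management system
#'
#' The signed influence diagram linking GDP, the environmental-investment
#' budget, the five treatment investments (air, solid waste, water,
#' vegetation, land), the resulting quality/pollution indicators, pollution
#' control cost, mining revenue and overall ecological quality. Investments
#' raise quality-type indicators and lower pollution indices; quality
#' indicators lower control cost and raise ecological quality; pollution
#' indices do the opposite; cost lowers mining revenue; revenue raises GDP;
#' GDP raises the environmental investment, while a high ecological quality
#' relaxes it. Its ten elementary loops split into five reinforcing loops
#' (through the cost-revenue-GDP path) and five balancing ones (through
#' ecological quality).
#'
#' @return A [signed_digraph()] with 15 nodes and 24 edges.
#' @export
mining_cld <- function() {
  E <- function(from, to, sign) data.frame(from = from, to = to, sign = sign)
  qual <- c(air = "air_quality",
            solid = "solid_pollution_index",
            water = "water_pollution_index",
            vegetation = "vegetation_greening_rate",
            land = "land_reclamation_rate")
  inv <- c(air = "investment_air", solid = "investment_solid",
           water = "investment_water", vegetation = "investment_vegetation",
           land = "investment_land")
  # pollution indices are "bad" indicators: investment lowers them, they raise
  # cost and lower ecological quality; quality-type indicators are "good".
  bad <- c(FALSE, TRUE, TRUE, FALSE, FALSE)
  edges <- rbind(
    E("gdp", "environmental_investment", 1L),
    E("environmental_investment", unname(inv), 1L),
    E(unname(inv), unname(qual), ifelse(bad, -1L, 1L)),
    E(unname(qual), "pollution_control_cost", ifelse(bad, 1L, -1L)),
    E(unname(qual), "ecological_environment_quality", ifelse(bad, -1L, 1L)),
    E("pollution_control_cost", "mining_revenue", -1L),
    E("mining_revenue", "gdp", 1L),
    E("ecological_environment_quality", "environmental_investment", -1L)
  )
  signed_digraph(edges)
}

#' Read / write a signed digraph as a plain-text edge list
#'
#' One edge per line: `source<TAB>target<TAB>+|-`. The round trip is exact.
#'
#' @param path File path.
#' @return `read_cld()` returns a [signed_digraph()]; `write_cld()` returns
#'   `path` invisibly.
#' @export
read_cld <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed edge-list line(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  m <- do.call(rbind, parts)
  signed_digraph(data.frame(from = m[, 1L], to = m[, 2L], sign = m[, 3L]))
}

#' @rdname read_cld
#' @param graph A [signed_digraph()].
#' @export
write_cld <- function(graph, path) {
  stopifnot(inherits(graph, "signed_digraph"))
  writeLines(sprintf("%s\t%s\t%s", graph$edges$from, graph$edges$to,
                     ifelse(graph$edges$sign > 0L, "+", "-")), path)
  invisible(path)
}
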