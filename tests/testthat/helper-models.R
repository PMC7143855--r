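# Shared fixtures and independent oracles.

# Single linear stock: constant production P (inflow), removal fraction p of
# the current stock (outflow).
one_stock_model <- function(X0 = 300, P = 4824, p = 0.4) {
  sd_model(
    constants = list(sd_constant("production", P),
                     sd_constant("removal_fraction", p)),
    rates = list(
      sd_rate("production_rate", "production", "inflow", "pollution"),
      sd_rate("treatment_rate", "pollution * removal_fraction",
              "outflow", "pollution")),
    stocks = list(sd_stock("pollution", X0)))
}

# Closed form of the geometric recursion X[t+1] = X[t] + dt*(P - p*X[t]):
# X(t) = P/p + (X0 - P/p) * (1 - p*dt)^t  (p > 0), X0 + t*dt*P otherwise.
linear_stock_closed_form <- function(X0, P, p, t, dt = 1) {
  if (p == 0) return(X0 + t * dt * P)
  P / p + (X0 - P / p) * (1 - p * dt)^t
}

# Independent brute-force elementary-cycle oracle: grow simple paths from
# every start node and record closures, deduplicating by canonical rotation.
oracle_cycles <- function(graph) {
  adj <- split(graph$edges$to, factor(graph$edges$from, levels = graph$nodes))
  found <- new.env(parent = emptyenv())
  grow <- function(path) {
    tips <- adj[[path[length(path)]]]
    for (w in tips) {
      if (w == path[1L]) {
        i <- match(min(path), path)
        canon <- c(path[i:length(path)], path[seq_len(i - 1L)])
        assign(paste(canon, collapse = "\001"), canon, envir = found)
      } else if (!(w %in% path)) {
        grow(c(path, w))
      }
    }
  }
  for (v in graph$nodes) grow(v)
  keys <- sort(ls(found), method = "radix")
  lapply(keys, function(k) get(k, envir = found))
}

# Random signed digraph on n nodes (no self-loops, no parallel edges).
random_signed_digraph <- function(n, edge_prob = 0.3) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < edge_prob
  e <- pairs[keep, , drop = FALSE]
  if (!nrow(e)) e <- pairs[1L, , drop = FALSE]
  e$sign <- sample(c(-1L, 1L), nrow(e), replace = TRUE)
  signed_digraph(e)
}

loop_nodes <- function(loops) lapply(loops, `[[`, "nodes")
loop_polarities <- function(loops) vapply(loops, `[[`, character(1), "polarity")
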