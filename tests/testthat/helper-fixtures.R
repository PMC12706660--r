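# shared fixtures; the expensive calibrated study is computed once per test run
.fixtures <- new.env(parent = emptyenv())

cached_study <- function() {
  if (is.null(.fixtures$study)) .fixtures$study <- run_study()
  .fixtures$study
}

cached_params <- function() cached_study()$params

# single-segment, single-outlet toy: inlet -> out through one vessel
toy_single <- function(length = 0.1, radius = 0.005,
                       fluid = fluid_properties()) {
  arterial_network(
    data.frame(id = "s1", from = "in", to = "out",
               length = length, radius = radius),
    inlet_node = "in",
    outlets = data.frame(node = "out", name = "only"),
    fluid = fluid)
}

# symmetric two-outlet toy: inlet -> junction, then two identical branches
toy_two <- function(fluid = fluid_properties()) {
  arterial_network(
    data.frame(id = c("trunk", "b1", "b2"),
               from = c("in", "j", "j"),
               to = c("j", "o1", "o2"),
               length = c(0.1, 0.08, 0.08),
               radius = c(0.008, 0.004, 0.004)),
    inlet_node = "in",
    outlets = data.frame(node = c("o1", "o2"), name = c("left", "right")),
    fluid = fluid)
}

# independent Poiseuille path-resistance oracle: brute-force walk over the
# undirected edge list, accumulating 8*mu*L/(pi*r^4) from first principles
oracle_path_resistance <- function(network, target) {
  seg <- network$segments
  mu <- network$fluid$viscosity
  edges <- lapply(seq_len(nrow(seg)), function(i)
    list(a = seg$from[i], b = seg$to[i],
         r = 8 * mu * seg$length[i] / (pi * seg$radius[i]^4)))
  walk <- function(node, from_node, acc) {
    if (node == target) return(acc)
    for (e in edges) {
      nxt <- if (e$a == node) e$b else if (e$b == node) e$a else NA
      if (!is.na(nxt) && !identical(nxt, from_node)) {
        got <- walk(nxt, node, acc + e$r)
        if (!is.na(got)) return(got)
      }
    }
    NA_real_
  }
  walk(network$inlet_node, NULL, 0)
}

# independent steady-state (Ohmic) oracle: dense nodal conductance system
# assembled from Ohm's law, with each outlet grounded through Rp+Rd to Pv
oracle_steady_state <- function(network, wk, q_in, q_lvad = 0) {
  seg <- network$segments
  nodes <- unique(c(seg$from, seg$to))
  n <- length(nodes)
  G <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(seg))) {
    g <- 1 / (8 * network$fluid$viscosity * seg$length[i] /
                (pi * seg$radius[i]^4))
    a <- seg$from[i]; b <- seg$to[i]
    G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
  }
  rhs <- setNames(numeric(n), nodes)
  rhs[network$inlet_node] <- q_in
  if (q_lvad > 0) rhs[network$lvad$source_node] <- q_lvad
  for (k in seq_len(nrow(network$outlets))) {
    nd <- network$outlets$node[k]
    i <- match(network$outlets$name[k], wk$outlet)
    rtot <- wk$Rp[i] + wk$Rd[i]
    G[nd, nd] <- G[nd, nd] + 1 / rtot
    rhs[nd] <- rhs[nd] + wk$Pv[i] / rtot
  }
  P <- solve(G, rhs)
  Q <- vapply(seq_len(nrow(seg)), function(i) {
    r <- 8 * network$fluid$viscosity * seg$length[i] / (pi * seg$radius[i]^4)
    (P[seg$from[i]] - P[seg$to[i]]) / r
  }, numeric(1))
  list(P = P, Q = setNames(Q, seg$id))
}

# numeric trapezoid, written independently of the package internals
num_trapz <- function(t, y) sum((y[-1] + y[-length(y)]) * diff(t)) / 2
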