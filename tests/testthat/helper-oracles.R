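# Independent brute-force oracles used to check the package's fast paths.

# O(n^2) segment-intersection test for polygon simplicity (pure R)
oracle_is_simple <- function(v) {
  n <- nrow(v)
  seg <- function(i) list(p = v[i, ], q = v[if (i == n) 1L else i + 1L, ])
  orient <- function(a, b, c) {
    d <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    if (abs(d) < 1e-12 * (abs(b[1] - a[1]) * abs(c[2] - a[2]) +
                          abs(b[2] - a[2]) * abs(c[1] - a[1]) + 1e-300)) 0 else sign(d)
  }
  for (i in seq_len(n - 1)) {
    si <- seg(i)
    for (j in (i + 1):n) {
      # skip segments sharing an endpoint
      if (j == i + 1 || (i == 1 && j == n)) next
      sj <- seg(j)
      o1 <- orient(si$p, si$q, sj$p); o2 <- orient(si$p, si$q, sj$q)
      o3 <- orient(sj$p, sj$q, si$p); o4 <- orient(sj$p, sj$q, si$q)
      if (o1 * o2 < 0 && o3 * o4 < 0) return(FALSE)
    }
  }
  TRUE
}

# plain-R point-to-polyline distance
oracle_dist_to_chain <- function(p, chain) {
  best <- Inf
  for (j in seq_len(nrow(chain) - 1)) {
    a <- chain[j, ]; b <- chain[j + 1, ]
    v <- b - a
    L2 <- sum(v^2)
    t <- if (L2 > 0) max(0, min(1, sum((p - a) * v) / L2)) else 0
    best <- min(best, sqrt(sum((p - a - t * v)^2)))
  }
  best
}

# rectangle outline helper for benchmark problems
rect_outline <- function(w, h, crown_root_y = h / 2) {
  read_outline_xy(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
                  crown_root_y = crown_root_y, label = "rect")
}

# nodes on a vertical line x = x0 of a rectangle mesh
nodes_at_x <- function(mesh, x0, tol = 1e-9) which(abs(mesh$coords[, 1] - x0) < tol)

# a small solved tooth model shared across tests
solved_tooth <- local({
  cache <- NULL
  function(target = 3000) {
    if (!is.null(cache)) return(cache)
    p <- otodontid_tooth_presets()
    o <- generate_outline(spec_from_row(p[p$label == "O. megalodon|lateral", ]))
    m <- identify_sets(triangulate(o, target), o)
    mat <- material()
    load <- build_load_case("draw", m, 500)
    cache <<- list(outline = o, mesh = m, material = mat, load = load,
                   solution = fe_solve(m, mat, load))
    cache
  }
})
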