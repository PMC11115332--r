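# Shared fixtures and independent oracles for the test suite.

# random TFN with support inside [lo, hi]
rand_tfn <- function(lo = 0, hi = 10) {
  tfn(sort(stats::runif(3, lo, hi)))
}

# Analytic centroid cross-check by adaptive quadrature of the triangle
# membership function: centroid = int x mu(x) dx / int mu(x) dx.
numeric_centroid <- function(t) {
  a <- t[[1]]; b <- t[[2]]; g <- t[[3]]
  mu <- function(x) tfn_membership(t, x)
  pieces <- function(f) {
    left <- if (b > a) stats::integrate(f, a, b, rel.tol = 1e-12)$value else 0
    right <- if (g > b) stats::integrate(f, b, g, rel.tol = 1e-12)$value else 0
    left + right
  }
  if (a == g) return(a)  # crisp: point mass
  pieces(function(x) x * mu(x)) / pieces(mu)
}

# Independent straightforward Mamdani implementation used as an oracle:
# plain loops, membership evaluated from the raw (alpha, beta, gamma)
# triples without calling the package's membership or inference code.
oracle_mamdani <- function(rules, input_scales, output_scale,
                           inputs, out_range, n_grid) {
  tri <- function(v, x) {
    a <- v[1]; b <- v[2]; g <- v[3]
    if (x < a || x > g) return(0)
    if (x == b) return(1)
    if (x < b) return((x - a) / (b - a))
    (g - x) / (g - b)
  }
  term_tfn <- function(scale, label) {
    i <- which(tolower(scale$labels) == tolower(label))
    as.numeric(unclass(scale$tfns[[i]]))
  }
  xs <- seq(out_range[1], out_range[2], length.out = n_grid)
  agg <- rep(0, n_grid)
  any_fired <- FALSE
  for (r in rules) {
    degs <- numeric(0)
    for (vn in names(r$antecedents)) {
      degs <- c(degs, tri(term_tfn(input_scales[[vn]], r$antecedents[[vn]]),
                          inputs[[vn]]))
    }
    s <- if (r$op == "AND") min(degs) else max(degs)
    if (s <= 0) next
    any_fired <- TRUE
    cons <- term_tfn(output_scale, r$consequent)
    for (i in seq_len(n_grid)) {
      agg[i] <- max(agg[i], min(tri(cons, xs[i]), s))
    }
  }
  if (!any_fired) return(NA_real_)
  sum(xs * agg) / sum(agg)
}

# decision matrix with one componentwise-dominant alternative on top
dominant_matrix <- function(n_alt = 4, n_crit = 3) {
  rows <- vector("list", n_alt)
  rows[[1]] <- replicate(n_crit, tfn(8, 9, 10), simplify = FALSE)
  for (i in 2:n_alt) {
    rows[[i]] <- replicate(n_crit, {
      base <- stats::runif(1, 1, 6)
      tfn(base, base + 1, base + 2)
    }, simplify = FALSE)
  }
  fuzzy_decision_matrix(rows, paste0("A", seq_len(n_alt)),
                        paste0("c", seq_len(n_crit)))
}
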