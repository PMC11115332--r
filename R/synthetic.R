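#' Synthetic risk registers
#'
#' Generates a reproducible expert-rated risk register for testing and
#' simulation. A chosen fraction of the failure modes form a dominance
#' chain: their linguistic grades decrease componentwise (strictly on
#' occurrence and severity) from the first chain member to the last, so the
#' ground-truth risk ordering of the chain is known by construction and any
#' sound ranker must recover it. The remaining failure modes draw their
#' grades uniformly over the scale categories. Expert-level noise jitters
#' each expert's label by one category up or down with the given
#' probability.
#'
#' Defaults mirror the study conditions of the worked example: twenty
#' failure modes rated by a five-expert panel with uniform weights.
#'
#' @param n_failure_modes Number of failure modes (>= 2).
#' @param n_experts Number of experts (uniform weights).
#' @param scales Scale registry.
#' @param dominance_fraction Fraction of failure modes placed in the
#'   dominance chain (rounded; chain length is capped at the occurrence
#'   ladder length so the chain stays strictly ordered).
#' @param noise Probability that an expert's label is jittered by one
#'   category.
#' @param seed Integer seed; the same seed yields an identical register.
#' @return A [risk_register()] with the chain ids in
#'   `attr(, "dominance_chain")` (riskiest first).
#' @export
generate_register <- function(n_failure_modes = 20L, n_experts = 5L,
                              scales = default_scales(),
                              dominance_fraction = 0.3, noise = 0.1,
                              seed = 1L) {
  stopifnot(n_failure_modes >= 2L, n_experts >= 1L,
            dominance_fraction >= 0, dominance_fraction <= 1,
            noise >= 0, noise <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  sizes <- vapply(scales[c("occurrence", "severity", "detection")],
                  function(s) length(s$labels), integer(1))
  n_chain <- min(round(dominance_fraction * n_failure_modes),
                 min(sizes[["occurrence"]], sizes[["severity"]]))
  ids <- paste0("FM", seq_len(n_failure_modes))
  chain_ids <- if (n_chain >= 1L) ids[seq_len(n_chain)] else character(0)

  # ordinal grade index per (fm, factor); chain members descend from the top
  base_idx <- matrix(NA_integer_, n_failure_modes, 3L,
                     dimnames = list(ids, c("occurrence", "severity", "detection")))
  for (f in 1:3) {
    n_lvl <- sizes[f]
    if (n_chain >= 1L) {
      base_idx[seq_len(n_chain), f] <-
        pmax(n_lvl - seq_len(n_chain) + 1L, 1L)
    }
    rest <- setdiff(seq_len(n_failure_modes), seq_len(n_chain))
    if (length(rest)) {
      base_idx[rest, f] <- sample.int(n_lvl, length(rest), replace = TRUE)
    }
  }

  experts <- paste0("E", seq_len(n_experts))
  rows <- expand.grid(fm_id = ids, expert_id = experts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (f in c("occurrence", "severity", "detection")) {
    n_lvl <- sizes[[f]]
    idx <- base_idx[rows$fm_id, f]
    jitter <- stats::runif(nrow(rows)) < noise
    idx[jitter] <- pmin(pmax(idx[jitter] +
                               sample(c(-1L, 1L), sum(jitter), replace = TRUE),
                             1L), n_lvl)
    rows[[f]] <- scales[[f]]$labels[idx]
  }
  reg <- risk_register(rows)
  attr(reg, "dominance_chain") <- chain_ids
  reg
}
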