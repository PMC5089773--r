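# Local weighted-digraph measures of the connectivity matrix. All three
# operate on the absolute connectivity W = |gamma| with self-loops removed;
# shortest-path lengths use the standard connectivity-toolbox mapping
# length = 1/weight.

prep_weights <- function(W) {
  W <- abs(as.matrix(W))
  if (nrow(W) != ncol(W)) stop("W must be square")
  diag(W) <- 0
  W
}

#' Local weighted clustering coefficient (directed)
#'
#' `C_m = [ (W^(1/3) + t(W)^(1/3))^3 ]_mm / (2 [d_tot (d_tot - 1) - 2 d_rec])`
#' where `d_tot` is the binary total (in+out) degree and `d_rec` the number
#' of reciprocated neighbours. Nodes with `d_tot <= 1` (degenerate
#' denominator) get `C_m = 0`.
#'
#' @param W non-negative weight matrix (signs and self-loops are stripped).
#' @return Per-node clustering coefficients.
#' @export
clustering_coefficient <- function(W) {
  W <- prep_weights(W)
  A <- (W > 0) * 1
  Wh <- W^(1/3)
  S <- Wh + t(Wh)
  num <- diag(S %*% S %*% S)
  d_tot <- rowSums(A) + colSums(A)
  d_rec <- diag(A %*% A)
  den <- 2 * (d_tot * (d_tot - 1) - 2 * d_rec)
  out <- ifelse(den > 0, num / den, 0)
  names(out) <- rownames(W)
  out
}

# all-pairs shortest weighted path lengths (length = 1/weight) and exact
# path counts, Floyd-Warshall style with tolerance-merged ties
shortest_paths_counts <- function(W, rel_tol = 1e-12) {
  W <- prep_weights(W)
  N <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  cnt <- ifelse(W > 0, 1, 0)
  diag(cnt) <- 0
  for (k in seq_len(N)) {
    for (i in seq_len(N)) {
      if (i == k || !is.finite(L[i, k])) next
      for (j in seq_len(N)) {
        if (j == k || j == i || !is.finite(L[k, j])) next
        via <- L[i, k] + L[k, j]
        if (via < L[i, j] * (1 - rel_tol)) {
          L[i, j] <- via
          cnt[i, j] <- cnt[i, k] * cnt[k, j]
        } else if (is.finite(L[i, j]) &&
                   abs(via - L[i, j]) <= rel_tol * max(via, L[i, j])) {
          cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
        }
      }
    }
  }
  list(lengths = L, counts = cnt)
}

#' Local efficiency
#'
#' `E_m = (1/(N-1)) sum_{j != m} 1 / l(m -> j)` with `l` the shortest
#' weighted path length (`length = 1/weight`); unreachable targets
#' contribute zero, so isolated nodes have `E_m = 0`.
#'
#' @inheritParams clustering_coefficient
#' @return Per-node efficiencies.
#' @export
local_efficiency <- function(W) {
  W <- prep_weights(W)
  N <- nrow(W)
  if (N < 2) return(structure(rep(0, N), names = rownames(W)))
  L <- shortest_paths_counts(W)$lengths
  inv <- 1 / L
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  out <- rowSums(inv) / (N - 1)
  names(out) <- rownames(W)
  out
}

#' Local weighted betweenness centrality
#'
#' `B_m = (1/((N-1)(N-2))) sum_{h != j, h != m, j != m} rho_hj(m) / rho_hj`
#' where `rho_hj` counts shortest weighted paths from `h` to `j` and
#' `rho_hj(m)` those passing through `m`. Multiple shortest paths are
#' counted exactly, with float ties merged at relative tolerance 1e-12.
#'
#' @inheritParams clustering_coefficient
#' @return Per-node betweenness values in `[0, 1]`.
#' @export
betweenness_centrality <- function(W) {
  W <- prep_weights(W)
  N <- nrow(W)
  if (N < 3) return(structure(rep(0, N), names = rownames(W)))
  sp <- shortest_paths_counts(W)
  L <- sp$lengths
  cnt <- sp$counts
  rel_tol <- 1e-12
  B <- numeric(N)
  for (m in seq_len(N)) {
    acc <- 0
    for (h in seq_len(N)) {
      if (h == m) next
      for (j in seq_len(N)) {
        if (j == m || j == h) next
        if (!is.finite(L[h, j]) || cnt[h, j] == 0) next
        via <- L[h, m] + L[m, j]
        if (is.finite(via) &&
            abs(via - L[h, j]) <= rel_tol * max(via, L[h, j])) {
          acc <- acc + (cnt[h, m] * cnt[m, j]) / cnt[h, j]
        }
      }
    }
    B[m] <- acc / ((N - 1) * (N - 2))
  }
  names(B) <- rownames(W)
  B
}

#' All three local topology metrics of a connectivity matrix
#'
#' @param gamma signed connectivity matrix (absolute values are used).
#' @return Data frame with `node`, `clustering`, `efficiency`,
#'   `betweenness`.
#' @export
topology_metrics <- function(gamma) {
  W <- prep_weights(gamma)
  nodes <- rownames(W)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(W)))
  data.frame(node = nodes,
             clustering = as.numeric(clustering_coefficient(W)),
             efficiency = as.numeric(local_efficiency(W)),
             betweenness = as.numeric(betweenness_centrality(W)),
             stringsAsFactors = FALSE)
}

#' Topology of populations by their coupling role
#'
#' Classifies every significant entry of the supplied coupling matrices as
#' direct (backed by a nonzero anatomical connection) or indirect, then
#' aggregates the topology metrics of sending and receiving nodes by role
#' and compares roles with two-sample t-tests. Also compares the mean
#' coupling strength of direct vs indirect entries.
#'
#' @param metrics a [topology_metrics()] data frame.
#' @param cfc one [estimate_cfc()] result or a list of them.
#' @param gamma the anatomical connectivity matrix.
#' @return List with `entries` (one row per significant coupling entry:
#'   source, target, value, role), `role_summary` (mean metric per role and
#'   endpoint), `tests` (t-test p-values comparing direct vs indirect
#'   sender/receiver metrics and strengths). Empty `entries` yields empty
#'   summaries.
#' @export
role_statistics <- function(metrics, cfc, gamma) {
  if (inherits(cfc, "cfc_result")) cfc <- list(cfc)
  anat <- prep_weights(gamma) > 0
  diag(anat) <- abs(diag(as.matrix(gamma))) > 0  # self-loops stay anatomical
  rows <- list()
  for (res in cfc) {
    sig <- which(res$mask, arr.ind = TRUE)
    if (nrow(sig) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      coupling = paste0(res$spec$type, "_", res$spec$source_band, "-",
                        res$spec$target_band),
      source = sig[, 1], target = sig[, 2],
      value = res$values[sig],
      role = ifelse(anat[sig], "direct", "indirect"),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(list(entries = data.frame(), role_summary = data.frame(),
                tests = list()))
  }
  entries <- do.call(rbind, rows)
  agg <- function(idx_col, metric) {
    tapply(metrics[[metric]][entries[[idx_col]]], entries$role, mean)
  }
  role_summary <- do.call(rbind, lapply(
    c("clustering", "efficiency", "betweenness"), function(mt) {
      data.frame(metric = mt,
                 endpoint = rep(c("sender", "receiver"), each = 1),
                 rbind(sender = agg("source", mt), receiver = agg("target", mt)),
                 stringsAsFactors = FALSE, check.names = FALSE)
    }))
  safe_t <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (sd(c(a, b)) == 0) return(NA_real_)
    tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
  }
  d <- entries$role == "direct"
  tests <- list(
    strength = safe_t(entries$value[d], entries$value[!d]),
    sender = lapply(c(clustering = "clustering", efficiency = "efficiency",
                      betweenness = "betweenness"), function(mt) {
      safe_t(metrics[[mt]][entries$source[d]],
             metrics[[mt]][entries$source[!d]])
    }),
    receiver = lapply(c(clustering = "clustering", efficiency = "efficiency",
                        betweenness = "betweenness"), function(mt) {
      safe_t(metrics[[mt]][entries$target[d]],
             metrics[[mt]][entries$target[!d]])
    }))
  list(entries = entries, role_summary = role_summary, tests = tests)
}
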