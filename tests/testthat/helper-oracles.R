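# Independent oracles used across the suite.
#
# The completion oracle evaluates a criterion tree two-valued over every
# completion of the unknown leaves and summarizes three ways; the engine
# under test must agree. The Fisher oracle recomputes the two-sided
# p-value from the plain factorial (choose) formula without logs.

# Two-valued evaluation of a tree over a completions-by-leaves logical
# matrix with columns named by leaf id.
oracle_eval_bool <- function(node, m) {
  switch(node$kind,
    threshold = ,
    flag = m[, node$id],
    all = Reduce(`&`, lapply(node$children, oracle_eval_bool, m)),
    any = Reduce(`|`, lapply(node$children, oracle_eval_bool, m)),
    at_least = {
      vals <- do.call(cbind, lapply(node$children, oracle_eval_bool, m))
      rowSums(vals) >= node$k
    },
    stop("oracle: unknown node kind ", node$kind))
}

# Three-way summary over all completions of the unknown leaves:
# TRUE iff every completion is TRUE, FALSE iff none is, NA otherwise.
oracle_tristate <- function(tree, leaf_states) {
  unknown <- names(leaf_states)[is.na(leaf_states)]
  n_completions <- 2^length(unknown)
  m <- matrix(rep(leaf_states, each = n_completions), nrow = n_completions,
              dimnames = list(NULL, names(leaf_states)))
  if (length(unknown) > 0) {
    grid <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(unknown))))
    m[, unknown] <- grid
  }
  vals <- oracle_eval_bool(tree, m)
  if (all(vals)) TRUE else if (!any(vals)) FALSE else NA
}

ruleset_leaves <- function(ruleset) {
  crsbiologic:::criterion_leaves(ruleset$tree)
}

# All 3^k assignments of {TRUE, FALSE, UNKNOWN} to the leaves of a rule
# set, realized as patient records: a threshold leaf is made TRUE with
# the cutoff value itself, FALSE with cutoff - 1, UNKNOWN by missingness.
leaf_state_grid <- function(ruleset) {
  leaves <- ruleset_leaves(ruleset)
  grid <- expand.grid(rep(list(c(TRUE, FALSE, NA)), length(leaves)))
  names(grid) <- names(leaves)
  grid
}

records_from_leaf_states <- function(ruleset, grid) {
  leaves <- ruleset_leaves(ruleset)
  cols <- list(patient_id = sprintf("G%05d", seq_len(nrow(grid))))
  for (id in names(leaves)) {
    leaf <- leaves[[id]]
    s <- grid[[id]]
    cols[[leaf$field]] <- if (leaf$kind == "threshold") {
      ifelse(is.na(s), NA_real_, ifelse(s, leaf$cutoff, leaf$cutoff - 1))
    } else {
      s
    }
  }
  tibble::as_tibble(cols)
}

# Engine-vs-oracle agreement on every node of a rule set, exhaustively
# over all leaf tristate assignments. Returns TRUE or stops with detail.
check_engine_against_oracle <- function(ruleset) {
  grid <- leaf_state_grid(ruleset)
  records <- records_from_leaf_states(ruleset, grid)
  states <- eval_criterion(ruleset$tree, records)
  nodes <- crsbiologic:::criterion_nodes(ruleset$tree)
  for (id in names(nodes)) {
    node <- nodes[[id]]
    leaf_ids <- names(crsbiologic:::criterion_leaves(node))
    expected <- vapply(seq_len(nrow(grid)), function(i) {
      ls <- vapply(leaf_ids, function(l) grid[[l]][i], logical(1))
      oracle_tristate(node, ls)
    }, logical(1))
    if (!identical(unname(states[[id]]), unname(expected))) {
      bad <- which(xor(is.na(states[[id]]), is.na(expected)) |
                   (!is.na(states[[id]]) & states[[id]] != expected))[1]
      stop(sprintf("engine/oracle mismatch at node '%s', case %d", id, bad))
    }
  }
  TRUE
}

# Two-sided Fisher p straight from the choose() formula (no logs).
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c; N <- m + n2
  s <- max(0, k - n2):min(k, m)
  p <- choose(m, s) * choose(n2, k - s) / choose(N, k)
  sum(p[p <= p[s == a] * (1 + 1e-7)])
}

# A small fully observed record meeting (or not) everything, for fixtures.
full_record <- function(patient_id = "P1", meets = TRUE,
                        biologic_initiated = FALSE) {
  if (meets) {
    tibble::tibble(patient_id = patient_id, n_ess = 2L, n_scs_past_year = 3L,
                   nps = 6L, snot22 = 80L, vas_tss = 90, vas_nb = 90,
                   vas_los = 90, bec = 400, ige = 300, asthma = TRUE,
                   biologic_initiated = biologic_initiated)
  } else {
    tibble::tibble(patient_id = patient_id, n_ess = 0L, n_scs_past_year = 0L,
                   nps = 0L, snot22 = 5L, vas_tss = 5, vas_nb = 5,
                   vas_los = 5, bec = 50, ige = 10, asthma = FALSE,
                   biologic_initiated = biologic_initiated)
  }
}
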