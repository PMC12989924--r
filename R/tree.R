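#' Grow a survival tree with a permutation-test splitting criterion
#'
#' Recursive binary partitioning of right-censored survival data. At each
#' node, a grid search over all covariates and feasible cutoffs evaluates the
#' two-sample CGE permutation test ([permutation_test()]) between the
#' candidate children \code{{z_j <= q}} and \code{{z_j > q}}; the split with
#' the smallest p-value is taken (ties broken by larger L1, then lower
#' covariate index, then lower cutoff) provided it does not exceed
#' \code{p_threshold}. The child with the larger integrated survival (positive
#' signed L1) is placed on the right, so better prognosis always moves right;
#' terminal nodes are numbered right to left, node 1 having the best
#' prognosis. Each terminal node carries the copula-graphic estimator fitted
#' to its training subjects.
#'
#' With \code{split_test = "logrank"} the same engine grows the classical
#' logrank-split comparator tree (Kaplan-Meier terminal curves, split chosen
#' by minimal chi-square p-value, orientation by the logrank score).
#'
#' @param data data frame containing \code{time_col}, \code{event_col} and
#'   covariate columns (all remaining columns). Categorical covariates must be
#'   pre-encoded numerically; missing values are not supported.
#' @param copula assumed [make_copula()] model for the CGE test and terminal
#'   curves.
#' @param p_threshold splitting stops when no candidate has p-value at or
#'   below this (default 0.01).
#' @param nperm permutations per candidate test.
#' @param min_child minimum child size of a feasible split.
#' @param seed integer root seed; per-node seeds are derived from the node
#'   path, so growth is reproducible and order-independent.
#' @param split_test \code{"cge"} (default) or \code{"logrank"}.
#' @param time_col,event_col column names of the observed time and the 0/1
#'   event indicator.
#' @return an object of class \code{cg_tree}.
#' @export
cg_tree <- function(data, copula = make_copula("independence"),
                    p_threshold = 0.01, nperm = 1000, min_child = 2,
                    seed, split_test = c("cge", "logrank"),
                    time_col = "time", event_col = "event") {
  split_test <- match.arg(split_test)
  if (nrow(data) < 1L) stop("empty data")
  stopifnot(time_col %in% names(data), event_col %in% names(data))
  covars <- setdiff(names(data), c(time_col, event_col, "group"))
  if (!length(covars)) stop("no covariate columns")
  z <- as.matrix(data[covars])
  if (anyNA(z) || anyNA(data[[time_col]]) || anyNA(data[[event_col]])) {
    stop("missing values are not supported; remove incomplete rows first")
  }
  time <- as.double(data[[time_col]])
  event <- as.integer(data[[event_col]])
  if (nrow(data) < 2 * min_child) {
    root <- make_terminal(seq_len(nrow(data)), time, event, copula, split_test)
  } else {
    root <- build_node(seq_len(nrow(data)), time, event, z, copula,
                       p_threshold, nperm, min_child, seed, split_test,
                       path = integer(0))
  }
  tree <- structure(list(root = root, covariates = covars, copula = copula,
                         p_threshold = p_threshold, nperm = nperm,
                         min_child = min_child, seed = seed,
                         split_test = split_test, n = nrow(data)),
                    class = "cg_tree")
  number_terminals(tree)
}

make_terminal <- function(idx, time, event, copula, split_test) {
  s <- surv_sample(time[idx], event[idx])
  curve <- if (split_test == "logrank") kaplan_meier(s) else
    copula_graphic(s, copula)
  list(type = "terminal", idx = idx, curve = curve,
       median_survival = median_survival(curve), size = length(idx))
}

build_node <- function(idx, time, event, z, copula, p_threshold, nperm,
                       min_child, seed, split_test, path) {
  node_seed <- derive_seed(seed, path, 7L)
  bs <- best_split(idx, time, event, z, copula, nperm, min_child,
                   node_seed, split_test)
  if (is.null(bs) || bs$p_value > p_threshold) {
    return(make_terminal(idx, time, event, copula, split_test))
  }
  low <- idx[z[idx, bs$covariate] <= bs$cutoff]
  high <- idx[z[idx, bs$covariate] > bs$cutoff]
  low_right <- bs$l1_signed > 0 # low child survives longer -> placed right
  kids <- list(low = low, high = high)
  right_idx <- if (low_right) kids$low else kids$high
  left_idx <- if (low_right) kids$high else kids$low
  grow <- function(ix, step) {
    if (length(ix) < 2 * min_child) {
      make_terminal(ix, time, event, copula, split_test)
    } else {
      build_node(ix, time, event, z, copula, p_threshold, nperm, min_child,
                 seed, split_test, path = c(path, step))
    }
  }
  list(type = "internal", covariate = bs$covariate,
       varname = colnames(z)[bs$covariate], cutoff = bs$cutoff,
       p_value = bs$p_value, l1 = bs$l1, l1_signed = bs$l1_signed,
       low_side = if (low_right) "right" else "left",
       left = grow(left_idx, 1L), right = grow(right_idx, 2L),
       size = length(idx))
}

#' Best split of a node by the permutation-test criterion
#'
#' Evaluates every (covariate, cutoff) candidate whose children both have at
#' least \code{min_child} rows. Candidate cutoffs are the sorted unique
#' covariate values within the node, excluding the maximum so the \code{>}
#' child is non-empty. Returns \code{NULL} when no candidate is feasible.
#'
#' @param idx row indices of the node.
#' @param time,event,z pooled training data (z a numeric matrix).
#' @param copula assumed copula (CGE test).
#' @param nperm permutations per candidate.
#' @param min_child minimum child size.
#' @param seed node seed.
#' @param split_test \code{"cge"} or \code{"logrank"}.
#' @return list with \code{covariate}, \code{cutoff}, \code{p_value},
#'   \code{l1}, \code{l1_signed}, \code{left_size}, \code{right_size}, or
#'   \code{NULL}.
#' @export
best_split <- function(idx, time, event, z, copula, nperm = 1000,
                       min_child = 2, seed = 1,
                       split_test = c("cge", "logrank")) {
  split_test <- match.arg(split_test)
  if (length(idx) < 2 * min_child) return(NULL)
  best <- NULL
  for (j in seq_len(ncol(z))) {
    vals <- sort(unique(z[idx, j]))
    if (length(vals) < 2) next
    for (q in vals[-length(vals)]) {
      low <- idx[z[idx, j] <= q]
      high <- idx[z[idx, j] > q]
      if (length(low) < min_child || length(high) < min_child) next
      d <- two_sample(surv_sample(time[low], event[low]),
                      surv_sample(time[high], event[high]))
      cand <- if (split_test == "cge") {
        tst <- permutation_test(d, copula, nperm = nperm,
                                seed = derive_seed(seed, j, which(vals == q)))
        list(p_value = tst$p_value, l1 = tst$l1, l1_signed = tst$l1_signed)
      } else {
        if (sum(event[c(low, high)]) == 0L) next
        lr <- tryCatch(weighted_logrank(d, "logrank"), error = function(e) NULL)
        if (is.null(lr)) next
        # positive score means excess events in the low child (worse survival)
        list(p_value = lr$p_value, l1 = lr$statistic, l1_signed = -lr$score)
      }
      if (is.null(best) || cand$p_value < best$p_value ||
          (cand$p_value == best$p_value && cand$l1 > best$l1)) {
        best <- c(cand, list(covariate = j, cutoff = q,
                             left_size = length(low),
                             right_size = length(high)))
      }
    }
  }
  best
}

# assign terminal numbers 1..K by right-first depth-first traversal
number_terminals <- function(tree) {
  counter <- 0L
  walk <- function(node) {
    if (node$type == "terminal") {
      counter <<- counter + 1L
      node$node_number <- counter
      return(node)
    }
    node$right <- walk(node$right)
    node$left <- walk(node$left)
    node
  }
  tree$root <- walk(tree$root)
  tree$n_terminal <- counter
  tree
}

#' Route a covariate vector to its terminal node
#'
#' @param tree a [cg_tree()].
#' @param z named numeric vector, matrix or data frame of covariates in
#'   training arity (columns matched by name when available).
#' @return integer vector of terminal node numbers (1 = best prognosis).
#' @export
assign_node <- function(tree, z) {
  zm <- as_covariate_matrix(tree, z)
  apply(zm, 1, function(row) {
    if (anyNA(row)) stop("missing covariate values are not supported")
    node <- tree$root
    while (node$type == "internal") {
      side_low <- row[node$covariate] <= node$cutoff
      node <- if (side_low == (node$low_side == "right")) node$right
              else node$left
    }
    node$node_number
  })
}

as_covariate_matrix <- function(tree, z) {
  p <- length(tree$covariates)
  if (is.data.frame(z)) z <- as.matrix(z)
  if (is.null(dim(z))) {
    if (length(z) != p) stop("covariate vector has wrong arity")
    z <- matrix(z, 1, p, dimnames = list(NULL, names(z)))
  }
  if (!is.null(colnames(z)) && all(tree$covariates %in% colnames(z))) {
    z <- z[, tree$covariates, drop = FALSE]
  } else if (ncol(z) != p) {
    stop("covariate matrix has wrong arity")
  }
  storage.mode(z) <- "double"
  z
}

#' Predict survival probabilities from a survival tree
#'
#' The prediction for a subject routed to terminal node k at time t is the
#' node's fitted CGE evaluated at \code{min(t, domain_max)} (constant
#' extrapolation beyond the node's last observed training time).
#'
#' @param object a [cg_tree()].
#' @param z covariates (one row per subject).
#' @param times evaluation times (non-negative).
#' @param ... unused.
#' @return matrix of survival probabilities, subjects in rows, times in
#'   columns.
#' @export
predict.cg_tree <- function(object, z, times, ...) {
  stopifnot(all(times >= 0))
  nodes <- assign_node(object, z)
  curves <- terminal_curves(object)
  out <- matrix(NA_real_, length(nodes), length(times))
  for (i in seq_along(nodes)) {
    cv <- curves[[nodes[i]]]
    out[i, ] <- curve_value(cv, pmin(times, cv$domain_max))
  }
  out
}

#' Collect terminal nodes of a tree
#'
#' @param tree a [cg_tree()].
#' @return list indexed by node number with each terminal's fields.
#' @export
terminal_nodes <- function(tree) {
  acc <- vector("list", tree$n_terminal)
  walk <- function(node) {
    if (node$type == "terminal") {
      acc[[node$node_number]] <<- node
    } else {
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  acc
}

terminal_curves <- function(tree) lapply(terminal_nodes(tree), `[[`, "curve")

#' Collect internal (splitting) nodes of a tree
#'
#' @param tree a [cg_tree()].
#' @return list of internal node records (covariate, cutoff, p_value, ...).
#' @export
internal_nodes <- function(tree) {
  acc <- list()
  walk <- function(node) {
    if (node$type == "internal") {
      acc[[length(acc) + 1L]] <<- node[c("covariate", "varname", "cutoff",
                                         "p_value", "l1", "l1_signed", "size")]
      walk(node$left); walk(node$right)
    }
  }
  walk(tree$root)
  acc
}

#' @export
print.cg_tree <- function(x, ...) {
  cat(sprintf("Survival tree (%s splits, %s), n = %d, %d terminal node(s)\n",
              x$split_test,
              if (x$split_test == "cge")
                sprintf("%s copula, tau = %.3g", x$copula$family, x$copula$tau)
              else "Kaplan-Meier leaves",
              x$n, x$n_terminal))
  show <- function(node, indent, label) {
    pad <- strrep("  ", indent)
    if (node$type == "terminal") {
      cat(sprintf("%s%s leaf #%d: n = %d, median = %.4g\n", pad, label,
                  node$node_number, node$size, node$median_survival))
    } else {
      cat(sprintf("%s%s split %s <= %.4g (p = %.4g)\n", pad, label,
                  node$varname, node$cutoff, node$p_value))
      show(node$left, indent + 1, "[L]")
      show(node$right, indent + 1, "[R]")
    }
  }
  show(x$root, 0, "")
  invisible(x)
}

#' Cross-validated selection of the assumed dependence parameter tau
#'
#' Grows CGE trees for each candidate tau over event-stratified K-fold
#' cross-validation and reports mean tree size, Harrell's C on terminal-node
#' ranks and the Kaplan-Meier-weighted integrated Brier score on the held-out
#' folds. Following the recommendation to select the assumed dependence by a
#' cross-validated concordance index (dependence parameters estimated from
#' competing-risks data have large variances), the largest-C (or smallest-IBS)
#' row guides the choice.
#'
#' @param data survival table as in [cg_tree()].
#' @param tau_grid candidate Kendall tau values (0 = independence).
#' @param folds number of folds (>= 2).
#' @param p_threshold,nperm,min_child tree parameters.
#' @param seed integer seed (fold assignment and tree growth).
#' @param time_col,event_col column names.
#' @return data.frame with one row per tau: \code{tau},
#'   \code{mean_terminal_nodes}, \code{mean_harrells_c}, \code{mean_ibs}.
#' @export
cv_select_tau <- function(data, tau_grid, folds = 10, p_threshold = 0.01,
                          nperm = 1000, min_child = 2, seed,
                          time_col = "time", event_col = "event") {
  stopifnot(folds >= 2)
  event <- as.integer(data[[event_col]])
  fold_id <- make_event_stratified_folds(event, folds, seed)
  rows <- lapply(tau_grid, function(tau) {
    cop <- if (tau == 0) make_copula("independence") else
      make_copula("clayton", tau)
    per_fold <- vapply(seq_len(folds), function(k) {
      tr <- which(fold_id != k); te <- which(fold_id == k)
      tree <- cg_tree(data[tr, , drop = FALSE], cop,
                      p_threshold = p_threshold, nperm = nperm,
                      min_child = min_child,
                      seed = derive_seed(seed, k, round(1000 * tau)),
                      time_col = time_col, event_col = event_col)
      covars <- data[te, tree$covariates, drop = FALSE]
      nodes <- assign_node(tree, covars)
      hc <- harrells_c(nodes, surv_sample(data[[time_col]][te], event[te]))
      grid <- sort(unique(c(data[[time_col]][tr], data[[time_col]][te])))
      cens <- censoring_curve(surv_sample(data[[time_col]][tr], event[tr]))
      preds <- predict(tree, covars, pmin(grid, max(data[[time_col]][te])))
      ibs <- integrated_brier(preds,
                              surv_sample(data[[time_col]][te], event[te]),
                              cens, grid)
      c(tree$n_terminal, hc, ibs)
    }, numeric(3))
    data.frame(tau = tau,
               mean_terminal_nodes = mean(per_fold[1, ]),
               mean_harrells_c = mean(per_fold[2, ]),
               mean_ibs = mean(per_fold[3, ]))
  })
  do.call(rbind, rows)
}

# event-stratified fold labels; re-drawn with the next sub-seed if a fold
# ends up without any event
make_event_stratified_folds <- function(event, folds, seed) {
  n <- length(event)
  for (attempt in 1:100) {
    id <- integer(n)
    ev <- which(event == 1L); ce <- which(event == 0L)
    id[ev] <- with_local_seed(derive_seed(seed, 11L, attempt),
                              sample(rep_len(seq_len(folds), length(ev))))
    id[ce] <- with_local_seed(derive_seed(seed, 12L, attempt),
                              sample(rep_len(seq_len(folds), length(ce))))
    if (all(vapply(seq_len(folds), function(k) sum(event[id == k]), 0L) > 0L) &&
        all(tabulate(id, folds) > 1L)) {
      return(id)
    }
  }
  stop("could not build event-stratified folds; too few events?")
}

#' Serialize a survival tree to JSON
#'
#' Produces a documented JSON representation: internal nodes carry
#' \code{type, covariate, cutoff, p_value, low_side, left, right}; terminal
#' nodes carry \code{type, node_number, size, median_survival} and the fitted
#' step curve (\code{times}, \code{values}, \code{domain_max}).
#'
#' @param tree a [cg_tree()].
#' @param path optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when written to file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  rec <- function(node) {
    if (node$type == "terminal") {
      list(type = "terminal", node_number = node$node_number,
           size = node$size, median_survival = node$median_survival,
           curve = list(times = node$curve$time, values = node$curve$surv,
                        domain_max = node$curve$domain_max))
    } else {
      list(type = "internal", covariate = node$varname, cutoff = node$cutoff,
           p_value = node$p_value, l1 = node$l1, l1_signed = node$l1_signed,
           low_side = node$low_side,
           left = rec(node$left), right = rec(node$right))
    }
  }
  obj <- list(split_test = tree$split_test, copula = tree$copula$family,
              tau = tree$copula$tau, p_threshold = tree$p_threshold,
              nperm = tree$nperm, min_child = tree$min_child,
              n = tree$n, n_terminal = tree$n_terminal, root = rec(tree$root))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Export a survival tree as Graphviz DOT
#'
#' @param tree a [cg_tree()].
#' @param path optional output file.
#' @return DOT source as a character string.
#' @export
tree_to_dot <- function(tree, path = NULL) {
  lines <- c("digraph cg_tree {", "  node [shape=box];")
  id <- 0L
  emit <- function(node) {
    id <<- id + 1L
    me <- id
    if (node$type == "terminal") {
      lines <<- c(lines, sprintf(
        "  n%d [label=\"node %d\\nn = %d\\nmedian = %s\"];", me,
        node$node_number, node$size,
        formatC(node$median_survival, digits = 3, format = "g")))
    } else {
      lines <<- c(lines, sprintf(
        "  n%d [label=\"%s <= %s\\np = %s\"];", me, node$varname,
        formatC(node$cutoff, digits = 4, format = "g"),
        formatC(node$p_value, digits = 3, format = "g")))
      l <- emit(node$left)
      r <- emit(node$right)
      lines <<- c(lines, sprintf("  n%d -> n%d;", me, l),
                  sprintf("  n%d -> n%d;", me, r))
    }
    me
  }
  emit(tree$root)
  lines <- c(lines, "}")
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) writeLines(out, path)
  out
}
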