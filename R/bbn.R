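#' Define a discrete network node
#'
#' @param name node name.
#' @param states ordered character vector of state labels (unique).
#' @param parents character vector of parent node names (possibly empty).
#' @param cpt numeric matrix of conditional probabilities: one row per
#'   combination of parent states, one column per state. Rows are ordered with
#'   the first-listed parent varying fastest (the `expand.grid` convention);
#'   a root node has a single row (its prior). Each row must sum to 1.
#' @return object of class `bbn_node`.
#' @export
bbn_node <- function(name, states, parents = character(0), cpt) {
  if (anyDuplicated(states)) stop("state labels must be unique for node ", name)
  cpt <- matrix(as.numeric(cpt), ncol = length(states))
  colnames(cpt) <- states
  structure(list(name = name, states = states, parents = parents, cpt = cpt),
            class = "bbn_node")
}

#' Assemble a discrete Bayesian network
#'
#' @param nodes list of [bbn_node()] objects.
#' @param validate check acyclicity and CPT normalization (default TRUE).
#' @return object of class `bbn`.
#' @export
bbn <- function(nodes, validate = TRUE) {
  names(nodes) <- vapply(nodes, function(nd) nd$name, character(1))
  net <- structure(list(nodes = nodes), class = "bbn")
  if (validate) validate_network(net, strict = TRUE)
  net
}

#' @export
print.bbn <- function(x, ...) {
  cat(sprintf("Discrete Bayesian network: %d nodes\n", length(x$nodes)))
  for (nd in x$nodes) {
    cat(sprintf("  %s [%s]%s\n", nd$name, paste(nd$states, collapse = "/"),
                if (length(nd$parents)) paste0(" <- ", paste(nd$parents, collapse = ", "))
                else ""))
  }
  invisible(x)
}

node_card <- function(net) {
  vapply(net$nodes, function(nd) length(nd$states), integer(1))
}

#' Validate a Bayesian network
#'
#' Checks that all parent references resolve, the directed graph is acyclic,
#' and every CPT has the right shape with rows summing to 1 (tolerance 1e-9).
#'
#' @param net a `bbn`.
#' @param strict raise an error on the first violation (default) instead of
#'   returning the report.
#' @return character vector of violation messages (empty when valid).
#' @export
validate_network <- function(net, strict = TRUE) {
  problems <- character(0)
  nm <- names(net$nodes)
  for (nd in net$nodes) {
    dangling <- setdiff(nd$parents, nm)
    if (length(dangling)) {
      problems <- c(problems, sprintf("node %s: dangling parents %s", nd$name,
                                      paste(dangling, collapse = ", ")))
    }
  }
  if (!length(problems)) {
    # Kahn's algorithm for acyclicity
    indeg <- setNames(integer(length(nm)), nm)
    children <- setNames(vector("list", length(nm)), nm)
    for (nd in net$nodes) {
      indeg[nd$name] <- length(nd$parents)
      for (p in nd$parents) children[[p]] <- c(children[[p]], nd$name)
    }
    queue <- nm[indeg == 0]
    seen <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
      for (ch in children[[v]]) {
        indeg[ch] <- indeg[ch] - 1L
        if (indeg[ch] == 0L) queue <- c(queue, ch)
      }
    }
    if (seen < length(nm)) {
      problems <- c(problems, sprintf("cycle involving nodes: %s",
                                      paste(nm[indeg > 0], collapse = ", ")))
    }
  }
  card <- node_card(net)
  for (nd in net$nodes) {
    if (!length(setdiff(nd$parents, nm))) {
      expected <- prod(card[nd$parents])
      if (nrow(nd$cpt) != expected) {
        problems <- c(problems,
                      sprintf("node %s: CPT has %d rows, expected %d", nd$name,
                              nrow(nd$cpt), expected))
      }
      bad <- which(abs(rowSums(nd$cpt) - 1) > 1e-9 | apply(nd$cpt < 0, 1, any))
      if (length(bad)) {
        problems <- c(problems,
                      sprintf("node %s: CPT row %d is not a distribution (sums to %.6g)",
                              nd$name, bad[1], rowSums(nd$cpt)[bad[1]]))
      }
    }
  }
  if (strict && length(problems)) stop(paste(problems, collapse = "; "))
  problems
}

# ---- evidence ---------------------------------------------------------------

# Split evidence into hard (single state label) and soft (numeric distribution
# over the node's states). Soft evidence replaces the prior of a root node.
check_evidence <- function(net, evidence) {
  hard <- list(); soft <- list()
  for (v in names(evidence)) {
    nd <- net$nodes[[v]]
    if (is.null(nd)) stop("evidence on unknown node: ", v)
    ev <- evidence[[v]]
    if (is.character(ev)) {
      if (!ev %in% nd$states) {
        stop(sprintf("invalid state '%s' for node %s", ev, v))
      }
      hard[[v]] <- ev
    } else {
      if (length(ev) != length(nd$states)) {
        stop(sprintf("soft evidence for %s must have %d entries", v,
                     length(nd$states)))
      }
      if (length(nd$parents)) {
        stop("soft evidence (prior replacement) is only supported on root nodes: ", v)
      }
      soft[[v]] <- normalize_marginal(setNames(as.numeric(ev), nd$states),
                                      paste("soft evidence for", v),
                                      warn_tol = Inf)
    }
  }
  list(hard = hard, soft = soft)
}

apply_soft_evidence <- function(net, soft) {
  for (v in names(soft)) {
    net$nodes[[v]]$cpt <- matrix(soft[[v]], nrow = 1,
                                 dimnames = list(NULL, net$nodes[[v]]$states))
  }
  net
}

# ancestral pruning: only ancestors of the query and evidence nodes affect the
# posterior; all other (barren) nodes integrate out to 1
ancestral_nodes <- function(net, keep) {
  out <- character(0)
  stack <- keep
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v %in% out) next
    out <- c(out, v)
    stack <- c(stack, net$nodes[[v]]$parents)
  }
  out
}

# ---- factor machinery for variable elimination ------------------------------

lin_index <- function(idx, dims) {
  stride <- cumprod(c(1, dims[-length(dims)]))
  as.vector((idx - 1) %*% stride) + 1L
}

node_factor <- function(nd, card) {
  vars <- c(nd$name, nd$parents)
  # array layout: node state varies fastest, then parents in listed order,
  # matching CPT rows where the first parent varies fastest
  list(vars = vars, values = as.vector(t(nd$cpt)))
}

factor_product <- function(f, g, card) {
  if (!length(f$vars)) return(list(vars = g$vars, values = f$values * g$values))
  if (!length(g$vars)) return(list(vars = f$vars, values = f$values * g$values))
  vars <- union(f$vars, g$vars)
  dims <- card[vars]
  n <- prod(dims)
  idx <- arrayInd(seq_len(n), dims)
  fi <- lin_index(idx[, match(f$vars, vars), drop = FALSE], card[f$vars])
  gi <- lin_index(idx[, match(g$vars, vars), drop = FALSE], card[g$vars])
  list(vars = vars, values = f$values[fi] * g$values[gi])
}

factor_marginalize <- function(f, v, card) {
  keep <- setdiff(f$vars, v)
  if (!length(keep)) return(list(vars = character(0), values = sum(f$values)))
  idx <- arrayInd(seq_along(f$values), card[f$vars])
  ki <- lin_index(idx[, match(keep, f$vars), drop = FALSE], card[keep])
  list(vars = keep, values = as.vector(rowsum(f$values, ki)))
}

factor_reduce <- function(f, v, state_i, card) {
  if (!v %in% f$vars) return(f)
  idx <- arrayInd(seq_along(f$values), card[f$vars])
  sel <- idx[, match(v, f$vars)] == state_i
  list(vars = setdiff(f$vars, v), values = f$values[sel])
}

#' Exact posterior marginal by variable elimination
#'
#' Computes the exact posterior distribution of one node given hard evidence
#' (observed states) and/or soft evidence (replacement prior distributions on
#' root nodes). Barren nodes are pruned; the elimination order follows a
#' min-degree heuristic unless overridden. Deterministic.
#'
#' @param net a valid `bbn`.
#' @param query node name.
#' @param evidence named list: state label (hard) or numeric distribution over
#'   the node's states (soft, root nodes only).
#' @param elim_order optional explicit elimination order (a permutation of the
#'   non-query variables to eliminate); the posterior does not depend on it.
#' @return named numeric distribution over the query node's states.
#' @export
infer_marginal <- function(net, query, evidence = list(), elim_order = NULL) {
  if (is.null(net$nodes[[query]])) stop("unknown query node: ", query)
  ev <- check_evidence(net, evidence)
  net <- apply_soft_evidence(net, ev$soft)
  card <- node_card(net)

  if (query %in% names(ev$hard)) {
    states <- net$nodes[[query]]$states
    return(setNames(as.numeric(states == ev$hard[[query]]), states))
  }

  keep <- ancestral_nodes(net, c(query, names(ev$hard)))
  factors <- lapply(net$nodes[keep], node_factor, card = card)
  for (v in names(ev$hard)) {
    si <- match(ev$hard[[v]], net$nodes[[v]]$states)
    factors <- lapply(factors, factor_reduce, v = v, state_i = si, card = card)
  }
  factors <- Filter(function(f) length(f$values) > 0, factors)

  to_elim <- setdiff(keep, c(query, names(ev$hard)))
  if (is.null(elim_order)) {
    # min-degree: repeatedly eliminate the variable appearing with the fewest
    # distinct neighbours across current factors
    order_out <- character(0)
    fv <- lapply(factors, `[[`, "vars")
    remaining <- to_elim
    while (length(remaining)) {
      degs <- vapply(remaining, function(v) {
        nb <- unique(unlist(fv[vapply(fv, function(vs) v %in% vs, logical(1))]))
        length(setdiff(nb, v))
      }, numeric(1))
      pick <- remaining[which.min(degs)]
      order_out <- c(order_out, pick)
      touched <- vapply(fv, function(vs) pick %in% vs, logical(1))
      newvars <- setdiff(unique(unlist(fv[touched])), pick)
      fv <- c(fv[!touched], list(newvars))
      remaining <- setdiff(remaining, pick)
    }
    elim_order <- order_out
  } else {
    if (!all(to_elim %in% elim_order)) {
      stop("elim_order must be a permutation of the eliminable variables")
    }
    # pruned (barren) variables in the supplied order are ignored
    elim_order <- intersect(elim_order, to_elim)
  }

  for (v in elim_order) {
    touched <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touched)) next
    prod_f <- Reduce(function(a, b) factor_product(a, b, card),
                     factors[touched])
    factors <- c(factors[!touched],
                 list(factor_marginalize(prod_f, v, card)))
  }
  res <- Reduce(function(a, b) factor_product(a, b, card), factors)
  if (length(res$vars) != 1 || res$vars != query) {
    res <- factor_marginalize(res, setdiff(res$vars, query), card)
  }
  z <- sum(res$values)
  if (z <= 0) stop("inconsistent evidence: zero probability")
  setNames(res$values / z, net$nodes[[query]]$states)
}

#' Posterior marginal by full-joint enumeration (reference oracle)
#'
#' Independently computes the same posterior as [infer_marginal()] by
#' materializing the full joint distribution row by row and summing. Intended
#' as a brute-force reference for small networks.
#'
#' @inheritParams infer_marginal
#' @param max_joint refuse joints larger than this many cells.
#' @return named numeric distribution over the query node's states.
#' @export
enumerate_joint <- function(net, query, evidence = list(), max_joint = 1e7) {
  ev <- check_evidence(net, evidence)
  net <- apply_soft_evidence(net, ev$soft)
  card <- node_card(net)
  if (prod(card) > max_joint) stop("joint distribution too large to enumerate")

  grid <- expand.grid(lapply(net$nodes, function(nd) nd$states),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(grid))
  for (nd in net$nodes) {
    xi <- match(grid[[nd$name]], nd$states)
    if (length(nd$parents)) {
      pid <- lapply(nd$parents, function(pp) {
        match(grid[[pp]], net$nodes[[pp]]$states)
      })
      row <- 1L
      mult <- 1L
      for (k in seq_along(nd$parents)) {
        row <- row + (pid[[k]] - 1L) * mult
        mult <- mult * card[[nd$parents[k]]]
      }
      p <- p * nd$cpt[cbind(row, xi)]
    } else {
      p <- p * nd$cpt[1, xi]
    }
  }
  for (v in names(ev$hard)) p[grid[[v]] != ev$hard[[v]]] <- 0
  z <- sum(p)
  if (z <= 0) stop("inconsistent evidence: zero probability")
  states <- net$nodes[[query]]$states
  out <- vapply(states, function(s) sum(p[grid[[query]] == s]), numeric(1)) / z
  setNames(out, states)
}

# ---- JSON serialization -----------------------------------------------------

#' Write / read a network as JSON
#'
#' The document lists nodes with their states, parents and CPT rows; rows are
#' ordered with the first-listed parent varying fastest, as stated in the
#' file's `row_order` header field.
#'
#' @param net a `bbn`.
#' @param path file path.
#' @export
bbn_to_json <- function(net, path) {
  doc <- list(
    format = "discrete-bbn",
    row_order = "first parent varies fastest (expand.grid convention)",
    nodes = lapply(unname(net$nodes), function(nd) {
      list(name = nd$name, states = as.list(nd$states),
           parents = as.list(nd$parents),
           cpt = lapply(seq_len(nrow(nd$cpt)), function(i) unname(nd$cpt[i, ])))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname bbn_to_json
#' @export
bbn_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(doc$nodes, function(nd) {
    cpt <- do.call(rbind, lapply(nd$cpt, function(r) as.numeric(unlist(r))))
    bbn_node(nd$name, unlist(nd$states),
             if (length(nd$parents)) unlist(nd$parents) else character(0), cpt)
  })
  bbn(nodes)
}
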