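# Shared discount-factor grid-search driver.
#
# cand: per-module candidate gamma vectors (length-1 for pinned modules).
# r_free/r_init: which rewards the inner convex solver estimates and the
# values of clamped ones (binary baseline clamps all, maxit = 0).
# search: "exhaustive" visits every combination; "staged" does an
# exhaustive pass on a uniformly thinned grid, then full-resolution passes
# in windows of width +/- stride around the best three coarse nodes.
gamma_search <- function(feats, cand, eta, lambda, r_init, r_free,
                         tol, maxit, search = "auto", node_budget = 20000,
                         grid_cap = 1e6, coarse_budget = 1500) {
  N <- length(cand)
  Gs <- lengths(cand)
  n_exh <- prod(Gs)
  if (search == "auto")
    search <- if (n_exh <= node_budget) "exhaustive" else "staged"
  if (search == "exhaustive" && n_exh > grid_cap)
    stop("exhaustive gamma grid has ", format(n_exh),
         " nodes (> grid_cap); use a coarser epsilon, fewer modules, or ",
         "search = \"staged\"")
  run <- function(nodes)
    cpp_grid_search(feats$dist, feats$obs, feats$T, feats$K, cand = cand,
                    nodes = nodes - 1L, eta = eta, lambda = lambda,
                    r_init = r_init, r_free = r_free, tol = tol,
                    maxit = maxit)
  if (search == "exhaustive") {
    nodes <- as.matrix(expand.grid(lapply(Gs, seq_len)))
    res <- run(nodes)
    visited <- nodes
    objs <- res$objectives
    best_r <- res$best_rewards
  } else {
    stride <- 1L
    while (prod(ceiling(Gs / stride)) > coarse_budget) stride <- stride + 1L
    coarse <- lapply(Gs, function(G) unique(c(seq(1L, G, by = stride), G)))
    visited <- as.matrix(expand.grid(coarse))
    res1 <- run(visited)
    objs <- res1$objectives
    best_obj <- res1$best_objective
    best_r <- res1$best_rewards
    # hierarchically refine around the best nodes at successively finer
    # strides until the full grid resolution is reached
    width <- stride
    for (s in unique(c(max(1L, stride %/% 2L), 1L))) {
      top <- order(objs, decreasing = TRUE)
      top <- top[seq_len(min(3L, length(top)))]
      cand_nodes <- unique(do.call(rbind, lapply(top, function(i)
        as.matrix(expand.grid(lapply(seq_len(N), function(j)
          unique(c(seq(max(1L, visited[i, j] - width),
                       min(Gs[j], visited[i, j] + width), by = s),
                   visited[i, j]))))))))
      keep <- !duplicated(rbind(visited, cand_nodes))[
        nrow(visited) + seq_len(nrow(cand_nodes))]
      cand_nodes <- cand_nodes[keep, , drop = FALSE]
      if (!nrow(cand_nodes)) { width <- s; next }
      resk <- run(cand_nodes)
      visited <- rbind(visited, cand_nodes)
      objs <- c(objs, resk$objectives)
      if (resk$best_objective > best_obj) {
        best_obj <- resk$best_objective
        best_r <- resk$best_rewards
      }
      width <- s
    }
  }
  k <- which.max(objs)
  best_idx <- visited[k, , drop = TRUE]
  list(gammas = vapply(seq_len(N), function(j) cand[[j]][best_idx[j]], 0),
       rewards = best_r, objective = objs[k],
       visited = visited, objectives = objs, search = search,
       n_nodes = nrow(visited))
}

# Best attained objective at each candidate gamma value, per module.
gamma_profile <- function(sr, cand, module_names) {
  do.call(rbind, lapply(seq_along(cand), function(j) {
    vals <- vapply(seq_along(cand[[j]]), function(gi) {
      sel <- sr$visited[, j] == gi
      if (any(sel)) max(sr$objectives[sel]) else NA_real_
    }, 0)
    data.frame(module = module_names[j], gamma = cand[[j]],
               objective = vals, stringsAsFactors = FALSE)
  }))
}

# One epsilon/4 local refinement pass around a best node.
refine_pass <- function(feats, gammas, rewards, eta, lambda, r_free, tol,
                        maxit, epsilon, gamma_max, objective) {
  cand <- lapply(gammas, function(g)
    unique(pmax(0, pmin(gamma_max, g + (-3:3) * epsilon / 4))))
  nodes <- as.matrix(expand.grid(lapply(cand, seq_along)))
  res <- cpp_grid_search(feats$dist, feats$obs, feats$T, feats$K,
                         cand = cand, nodes = nodes - 1L, eta = eta,
                         lambda = lambda, r_init = rewards,
                         r_free = r_free, tol = tol, maxit = maxit)
  if (res$best_objective > objective) {
    bi <- nodes[res$best_node, ]
    list(gammas = vapply(seq_along(cand), function(j) cand[[j]][bi[j]], 0),
         rewards = res$best_rewards, objective = res$best_objective)
  } else list(gammas = gammas, rewards = rewards, objective = objective)
}
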