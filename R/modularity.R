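# Barber bipartite modularity and its simulated-annealing maximization.

# Internal state: integer module ids mh (hollows) and ms (beetles) over the
# binary incidence b; Bmat = b - k_h k_s / L is the modularity kernel. Only
# cross-level pairs enter Q, so Q is bilinear in the two assignments.
barber_setup <- function(m) {
  b <- unclass_matrix(as_interaction(m)) > 0
  mode(b) <- "numeric"
  L <- sum(b)
  kh <- rowSums(b)
  ks <- colSums(b)
  list(b = b, L = L, Bmat = b - outer(kh, ks) / L)
}

q_of <- function(setup, mh, ms) {
  tot <- 0
  for (mod in intersect(unique(mh), unique(ms))) {
    tot <- tot + sum(setup$Bmat[mh == mod, ms == mod, drop = FALSE])
  }
  tot / setup$L
}

assignment_to_state <- function(m, modules) {
  stopifnot(is.data.frame(modules), all(c("node", "level", "module") %in% names(modules)))
  hollows <- modules[modules$level == "hollow", ]
  beetles <- modules[modules$level == "beetle", ]
  mh <- hollows$module[match(rownames(m), hollows$node)]
  ms <- beetles$module[match(colnames(m), beetles$node)]
  if (any(is.na(mh)) || any(is.na(ms))) {
    abort("`modules` must assign every hollow and beetle to a module.")
  }
  list(mh = as.integer(factor(mh, levels = unique(c(mh, ms)))),
       ms = as.integer(factor(ms, levels = unique(c(mh, ms)))))
}

#' Barber bipartite modularity of a given partition
#'
#' `Q = (1/L) * sum_(h,s) (b_hs - k_h k_s / L) * [module(h) == module(s)]`
#' over the binary incidence `b` with `L` total links: the excess of
#' within-module links over the degree-based expectation. The all-in-one
#' partition scores exactly 0.
#'
#' @inheritParams node_scores
#' @param modules A tibble with columns `node`, `level`
#'   (`"hollow"`/`"beetle"`), `module` covering every node.
#' @return Modularity Q.
#' @export
barber_modularity <- function(m, modules) {
  m <- as_interaction(m)
  st <- assignment_to_state(m, modules)
  q_of(barber_setup(m), st$mh, st$ms)
}

# Affinity of one node to a module: sum of its kernel row over the module's
# members at the other level.
node_affinity <- function(Bvec, other_modules, mod) {
  sum(Bvec[other_modules == mod])
}

sa_one_run <- function(setup, control) {
  R <- nrow(setup$b); S <- ncol(setup$b)
  n <- R + S
  mh <- sample.int(max(2, min(n, control$init_modules)), R, replace = TRUE)
  ms <- sample.int(max(2, min(n, control$init_modules)), S, replace = TRUE)
  q <- q_of(setup, mh, ms)
  best <- list(q = q, mh = mh, ms = ms)

  # Initial temperature from the spread of Q under random single moves.
  deltas <- vapply(seq_len(100), function(i) {
    if (runif(1) < R / n) {
      i <- sample.int(R, 1)
      tgt <- sample.int(max(c(mh, ms)) + 1, 1)
      Bv <- setup$Bmat[i, ]
      (node_affinity(Bv, ms, tgt) - node_affinity(Bv, ms, mh[i])) / setup$L
    } else {
      j <- sample.int(S, 1)
      tgt <- sample.int(max(c(mh, ms)) + 1, 1)
      Bv <- setup$Bmat[, j]
      (node_affinity(Bv, mh, tgt) - node_affinity(Bv, mh, ms[j])) / setup$L
    }
  }, numeric(1))
  temp <- max(sd(deltas), 1e-4)

  stall <- 0
  for (sweep in seq_len(control$max_sweeps)) {
    for (pick in sample.int(n, n)) {
      nmod <- max(c(mh, ms)) + 1L
      tgt <- sample.int(nmod, 1)
      if (pick <= R) {
        i <- pick
        if (tgt == mh[i]) next
        Bv <- setup$Bmat[i, ]
        dq <- (node_affinity(Bv, ms, tgt) - node_affinity(Bv, ms, mh[i])) / setup$L
        if (dq > 0 || runif(1) < exp(dq / temp)) {
          mh[i] <- tgt
          q <- q + dq
        }
      } else {
        j <- pick - R
        if (tgt == ms[j]) next
        Bv <- setup$Bmat[, j]
        dq <- (node_affinity(Bv, mh, tgt) - node_affinity(Bv, mh, ms[j])) / setup$L
        if (dq > 0 || runif(1) < exp(dq / temp)) {
          ms[j] <- tgt
          q <- q + dq
        }
      }
    }
    if (q > best$q + 1e-12) {
      best <- list(q = q, mh = mh, ms = ms)
      stall <- 0
    } else {
      stall <- stall + 1
    }
    if (stall >= control$patience) break
    temp <- temp * control$cooling
  }
  refine_partition(setup, best$mh, best$ms)
}

# Deterministic polish: greedy single-node moves to the best module, then
# greedy module merges, iterated to a local optimum.
refine_partition <- function(setup, mh, ms) {
  R <- nrow(setup$b); S <- ncol(setup$b)
  repeat {
    improved <- FALSE
    repeat {
      moved <- FALSE
      mods <- sort(unique(c(mh, ms)))
      for (i in seq_len(R)) {
        Bv <- setup$Bmat[i, ]
        aff <- vapply(mods, function(mod) node_affinity(Bv, ms, mod), numeric(1))
        cur <- match(mh[i], mods)
        bestm <- which.max(aff)
        if (aff[bestm] > aff[cur] + 1e-12) {
          mh[i] <- mods[bestm]; moved <- TRUE
        }
      }
      for (j in seq_len(S)) {
        Bv <- setup$Bmat[, j]
        aff <- vapply(mods, function(mod) node_affinity(Bv, mh, mod), numeric(1))
        cur <- match(ms[j], mods)
        bestm <- which.max(aff)
        if (aff[bestm] > aff[cur] + 1e-12) {
          ms[j] <- mods[bestm]; moved <- TRUE
        }
      }
      if (!moved) break
      improved <- TRUE
    }
    # merge phase on the module coupling matrix
    mods <- sort(unique(c(mh, ms)))
    k <- length(mods)
    if (k >= 2) {
      H <- outer(mh, mods, "==") * 1
      Sm <- outer(ms, mods, "==") * 1
      K <- t(H) %*% setup$Bmat %*% Sm
      gain <- (K + t(K)) / setup$L
      diag(gain) <- -Inf
      gmax <- max(gain)
      if (gmax > 1e-12) {
        ij <- which(gain == gmax, arr.ind = TRUE)[1, ]
        a <- mods[ij[1]]; bmod <- mods[ij[2]]
        mh[mh == bmod] <- a
        ms[ms == bmod] <- a
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  ids <- unique(c(mh, ms))
  list(q = q_of(setup, mh, ms),
       mh = match(mh, ids), ms = match(ms, ids))
}

#' Simulated-annealing control parameters
#'
#' @param restarts Independent annealing restarts (best Q kept).
#' @param max_sweeps Hard cap on sweeps per restart.
#' @param patience Stop a restart after this many sweeps without improvement.
#' @param cooling Geometric cooling factor applied after each sweep.
#' @param init_modules Number of modules in the random initial assignment.
#' @return A list of class `sa_control`.
#' @export
sa_control <- function(restarts = 8, max_sweeps = 500, patience = 50,
                       cooling = 0.95, init_modules = 10) {
  structure(
    list(restarts = restarts, max_sweeps = max_sweeps, patience = patience,
         cooling = cooling, init_modules = init_modules),
    class = "sa_control"
  )
}

#' Maximize Barber modularity by simulated annealing
#'
#' Anneals node-to-module assignments (single-node reassignment moves under
#' geometric cooling), polishes each restart with greedy moves and module
#' merges, and keeps the best partition over seeded restarts.
#'
#' @inheritParams node_scores
#' @param seed Integer seed; a fixed seed gives an identical partition.
#' @param control An [sa_control()] list.
#' @return A `module_partition`: list with `Q` and a `modules` tibble
#'   (`node`, `level`, `module`).
#' @export
maximize_modularity <- function(m, seed = NULL, control = sa_control()) {
  m <- as_interaction(m)
  setup <- barber_setup(m)
  best <- NULL
  for (r in seq_len(control$restarts)) {
    run_seed <- if (is.null(seed)) NULL else substream_seed(seed, paste0("sa", r))
    res <- with_seed(run_seed, sa_one_run(setup, control))
    if (is.null(best) || res$q > best$q + 1e-12) best <- res
  }
  modules <- dplyr::bind_rows(
    tibble::tibble(node = rownames(m), level = "hollow", module = best$mh),
    tibble::tibble(node = colnames(m), level = "beetle", module = best$ms)
  )
  structure(list(Q = best$q, modules = modules, n_modules = length(unique(modules$module))),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> Q = ", format(x$Q, digits = 4),
      ", ", x$n_modules, " modules over ", nrow(x$modules), " nodes\n", sep = "")
  invisible(x)
}

#' Modularity significance under the CE null model
#'
#' As [nestedness_significance()], but the statistic is the maximized Barber
#' Q of each CE null draw, so the p-value asks whether the observed web is
#' more modular than degree-proportional chance.
#'
#' @inheritParams nestedness_significance
#' @param control An [sa_control()]; the same optimizer settings are applied
#'   to the observed web and to every null draw.
#' @return A `null_ensemble` object with `statistic = "M"`.
#' @export
modularity_significance <- function(m, replicates = 100, seed = NULL,
                                    control = sa_control(restarts = 2, max_sweeps = 80, patience = 15)) {
  m <- as_interaction(m)
  p <- ce_null_probabilities(m)
  obs <- maximize_modularity(m, seed = if (is.null(seed)) NULL else substream_seed(seed, "obs"),
                             control = control)$Q
  nulls <- vapply(seq_len(replicates), function(i) {
    rs <- if (is.null(seed)) NULL else substream_seed(seed, paste0("null", i))
    b <- with_seed(rs, draw_ce_matrix(p))
    if (is.null(b)) {
      inform("CE draw still degenerate after retries; using it as drawn.")
      b <- with_seed(rs, matrix(runif(length(p)) < p, nrow(p)))
    }
    dimnames(b) <- dimnames(p)
    bm <- interaction_matrix(b * 1L, quiet = TRUE)
    maximize_modularity(bm, seed = rs, control = control)$Q
  }, numeric(1))
  new_null_ensemble(obs, nulls, "M")
}
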