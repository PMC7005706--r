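# STUN-BH global search: basin hopping whose Metropolis acceptance acts
# on a stochastically tunneled (nonlinearly flattened) energy surface.
# Each iteration perturbs the current configuration with a short
# high-temperature MD run, locally minimizes it, and accepts or rejects
# on the transformed energy; the transform reference tracks the best
# energy found so far, so barriers above it are compressed toward 1
# while the ordering and location of minima are preserved.

#' Stochastic-tunneling energy transform
#'
#' `f(E) = 1 - exp(-gamma * (E - E_ref))`: zero at the reference,
#' strictly increasing in E for any `gamma > 0`, bounded above by 1.
#' With `E_ref` maintained as the best energy seen, high barriers are
#' flattened while every local minimum keeps its location and relative
#' order.
#'
#' @param E Energy (vectorized), kcal/mol.
#' @param E_ref Reference energy (current best), kcal/mol.
#' @param gamma Tunneling parameter, 1/(kcal/mol).
#' @return Transformed energy.
#' @examples
#' stun_transform(0, 0, 1)                 # 0
#' stun_transform(log(2), 0, 1)            # 0.5
#' @export
stun_transform <- function(E, E_ref, gamma) {
  stopifnot(gamma > 0)
  1 - exp(-gamma * (E - E_ref))
}

#' STUN-BH search configuration
#'
#' @param n_starts Independent initial conformations (study default
#'   1000; desk-scale runs use far fewer).
#' @param iterations Basin-hopping iterations per start (study default
#'   200).
#' @param gamma Tunneling parameter; `NULL` auto-calibrates from the
#'   energy spread of the first iterations so a typical spread maps to
#'   f of about 0.9.
#' @param beta Inverse Metropolis temperature on the transformed
#'   (dimensionless) surface; the default 5 gives roughly half
#'   acceptance on the bundled toy fixtures.
#' @param perturb_md MD spec of the perturbation move: list with
#'   `temperature`, `n_steps`, `timestep_fs`, `thermostat` (defaults
#'   500 K, 300 steps, 2 fs, Nose-Hoover).
#' @param cg_tol,cg_max_iter Local-minimization controls.
#' @param height_range Initial placement window of the lowest peptide
#'   atom above the top slab layer (A).
#' @param dedup_de,dedup_rmsd Two minima are the same when their
#'   energies differ by less than `dedup_de` (kcal/mol) and their
#'   superposed mobile-atom RMSD is below `dedup_rmsd` (A).
#' @param seed Master seed; every stochastic element derives from it.
#' @return `stunbh_config` list.
#' @export
stunbh_config <- function(n_starts = 1000, iterations = 200, gamma = NULL,
                          beta = 5, perturb_md = list(),
                          cg_tol = 1e-3, cg_max_iter = 500,
                          height_range = c(3, 8),
                          dedup_de = 0.1, dedup_rmsd = 0.5, seed = 1) {
  stopifnot(n_starts >= 1, iterations >= 1)
  md_def <- list(temperature = 500, n_steps = 300, timestep_fs = 2,
                 thermostat = "nose_hoover")
  perturb_md <- utils::modifyList(md_def, perturb_md)
  structure(list(n_starts = as.integer(n_starts),
                 iterations = as.integer(iterations),
                 gamma = gamma, beta = beta, perturb_md = perturb_md,
                 cg_tol = cg_tol, cg_max_iter = cg_max_iter,
                 height_range = height_range,
                 dedup_de = dedup_de, dedup_rmsd = dedup_rmsd,
                 seed = as.integer(seed)),
            class = "stunbh_config")
}

#' Planned iteration count of a search schedule
#'
#' @param config `stunbh_config`.
#' @return `n_starts * iterations`.
#' @examples
#' planned_iterations(stunbh_config(1000, 200)) # 200000
#' @export
planned_iterations <- function(config) {
  as.numeric(config$n_starts) * as.numeric(config$iterations)
}

# ---- generic engine ----------------------------------------------------
# An objective is a list with:
#   minimize(state)         -> list(state, energy)
#   perturb(state, seed)    -> state
#   describe(state)         -> coordinate matrix (for deduplication) or NULL

#' STUN-BH iteration loop on an abstract objective
#'
#' The engine behind [stunbh_iterate()] and [multistart_search()],
#' exposed so surrogate objectives (analytic test surfaces, cluster
#' models) can be searched with exactly the production code path.
#'
#' @param objective List with functions `minimize(state)` returning
#'   `list(state =, energy =)` and `perturb(state, seed)` returning a
#'   new state.
#' @param start Initial state.
#' @param config `stunbh_config` (only `iterations`, `gamma`, `beta`,
#'   `seed` are used here).
#' @return List: `best_state`, `best_energy`, `trace` (energy per
#'   iteration), `accept_rate`, `gamma`.
#' @export
stunbh_core <- function(objective, start, config) {
  set.seed(config$seed)
  n_moves <- config$iterations - 1L  # iteration 1 minimizes the start
  iter_seeds <- if (n_moves > 0)
    sample.int(.Machine$integer.max - 1L, n_moves) else integer(0)
  cur <- objective$minimize(start)
  best <- cur
  e_ref <- best$energy
  gamma <- config$gamma
  trace <- numeric(config$iterations)
  trace[1] <- best$energy
  cal <- c(cur$energy)
  n_acc <- 0L
  for (it in seq_len(n_moves)) {
    cand_state <- objective$perturb(cur$state, iter_seeds[it])
    cand <- objective$minimize(cand_state)
    cal <- c(cal, cand$energy)
    # auto-calibration: track the observed spread for the first moves,
    # then freeze gamma so a typical spread maps to f ~ 0.9
    g_now <- if (is.null(gamma)) {
      spread <- diff(range(cal))
      g <- if (spread > 0) -log(1 - 0.9) / spread else 1
      if (it >= 10) gamma <- g
      g
    } else gamma
    df <- stun_transform(cand$energy, e_ref, g_now) -
      stun_transform(cur$energy, e_ref, g_now)
    if (df <= 0 || stats::runif(1) < exp(-config$beta * df)) {
      cur <- cand
      n_acc <- n_acc + 1L
    }
    if (cand$energy < best$energy) {
      best <- cand
      e_ref <- best$energy
    }
    trace[it + 1L] <- best$energy
  }
  list(best_state = best$state, best_energy = best$energy, trace = trace,
       accept_rate = if (n_moves > 0) n_acc / n_moves else NA_real_,
       gamma = if (is.null(gamma)) 1 else gamma)
}

# ---- molecular objective ----------------------------------------------

#' Perturbation move: short high-temperature MD
#'
#' Generates the next candidate configuration by running the configured
#' perturbation MD (defaults: 500 K, 300 steps, 2 fs) from the current
#' one.  Zero steps returns the input unchanged; identical seeds yield
#' identical candidates.
#'
#' @param system A `molsys`.
#' @param md_spec List: `temperature`, `n_steps`, `timestep_fs`,
#'   `thermostat`.
#' @param seed RNG seed for the move.
#' @param params `ff_params`.
#' @return Perturbed `molsys` (slab atoms untouched).
#' @export
perturb_move <- function(system, md_spec = list(), seed = 1,
                         params = default_forcefield()) {
  md_def <- list(temperature = 500, n_steps = 300, timestep_fs = 2,
                 thermostat = "nose_hoover")
  md_spec <- utils::modifyList(md_def, md_spec)
  if (md_spec$n_steps == 0) return(system)
  cfg <- md_config(timestep_fs = md_spec$timestep_fs,
                   n_steps = md_spec$n_steps,
                   temperature = md_spec$temperature,
                   thermostat = md_spec$thermostat,
                   seed = seed, stride = md_spec$n_steps)
  traj <- tryCatch(run_md(system, cfg, params), error = function(e) {
    # one velocity resample, then give up
    cfg$seed <- seed + 1L
    run_md(system, cfg, params)
  })
  traj$final_system
}

#' @keywords internal
.molecular_objective <- function(params, config) {
  list(
    minimize = function(state) {
      r <- local_minimize(state, params, tol = config$cg_tol,
                          max_iter = config$cg_max_iter)
      e <- if (!is.na(r$e_be)) r$e_be else r$e_total
      list(state = r$system, energy = e)
    },
    perturb = function(state, seed)
      perturb_move(state, config$perturb_md, seed, params),
    describe = function(state) state$coords[!state$atoms$fixed, , drop = FALSE]
  )
}

#' One STUN-BH search from a single start
#'
#' Loop: locally minimize, then repeatedly perturb by high-temperature
#' MD, re-minimize, and Metropolis-accept on the tunneled surface whose
#' reference is the best binding energy found so far.  The running best
#' is monotonically non-increasing.  Local minimization acts on the
#' total potential energy (with the substrate rigid this differs from
#' the binding energy only by the peptide's internal energy); ranking
#' and acceptance use the single-point binding energy evaluated after
#' each minimization.
#'
#' @param system Starting `molsys` (peptide on slab, or any system).
#' @param config `stunbh_config`.
#' @param params `ff_params`.
#' @return As [stunbh_core()], with `best_state` a `molsys`.
#' @export
stunbh_iterate <- function(system, config = stunbh_config(n_starts = 1),
                           params = default_forcefield()) {
  stunbh_core(.molecular_objective(params, config), system, config)
}

#' @keywords internal
.random_rotation <- function() {
  # uniform rotation via quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Randomly place a peptide above a slab
#'
#' Uniform rigid-body rotation, uniform lateral position in the surface
#' cell, base height of the lowest peptide atom drawn in
#' `config$height_range` above the top layer; lifted in 0.5 A steps
#' until no peptide-slab contact is closer than 2 A.
#'
#' @param peptide,slab `molsys` objects.
#' @param config `stunbh_config`.
#' @return Combined `molsys` (peptide + slab).
#' @export
place_peptide <- function(peptide, slab, config = stunbh_config(n_starts = 1)) {
  rot <- .random_rotation()
  xyz <- peptide$coords %*% t(rot)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  meta <- slab$slab
  lat <- stats::runif(2)
  lateral <- lat[1] * slab$cell[, 1] + lat[2] * slab$cell[, 2]
  h <- stats::runif(1, config$height_range[1], config$height_range[2])
  xyz[, 1] <- xyz[, 1] + lateral[1]
  xyz[, 2] <- xyz[, 2] + lateral[2]
  xyz[, 3] <- xyz[, 3] - min(xyz[, 3]) + meta$top_z + h
  pep <- peptide
  pep$coords <- xyz
  sys <- merge_systems(pep, slab)
  repeat {
    pmask <- sys$atoms$group == "peptide"
    d <- .min_cross_distance(sys$coords[pmask, , drop = FALSE],
                             sys$coords[!pmask, , drop = FALSE], sys$cell)
    if (d > 2.5) break
    sys$coords[pmask, 3] <- sys$coords[pmask, 3] + 0.5
  }
  sys
}

#' @keywords internal
.min_cross_distance <- function(xa, xb, cell) {
  best <- Inf
  Minv <- if (!is.null(cell)) solve(cell) else NULL
  for (i in seq_len(nrow(xa))) {
    d <- sweep(xb, 2, xa[i, ], `-`)
    if (!is.null(Minv)) {
      f <- d[, 1:2, drop = FALSE] %*% t(Minv)
      f <- f - round(f)
      d[, 1:2] <- f %*% t(cell)
    }
    best <- min(best, sqrt(min(rowSums(d^2))))
  }
  best
}

#' Multistart STUN-BH search
#'
#' Runs `config$n_starts` independent STUN-BH searches, each from a
#' random rigid-body placement of the peptide above the slab, with an
#' independent seed substream per start, then ranks and deduplicates
#' the per-start minima (same minimum when both the energy gap and the
#' superposed RMSD fall below the configured tolerances; first found is
#' kept).
#'
#' @param peptide Peptide `molsys` (or a sequence string /
#'   `peptide_sequence`, built with the extended preset).
#' @param slab Slab `molsys` from [build_fcc_slab()]; may be `NULL` for
#'   cluster-style objectives, in which case each start perturbs the
#'   input configuration.
#' @param config `stunbh_config`.
#' @param params `ff_params`.
#' @return `search_result`: `minima` (list of `system`, `e_be`,
#'   `multiplicity`, ascending energy), `best_per_start` data frame,
#'   `planned_iterations`, `completed_iterations`, `accept_rate`,
#'   `failures`, `seed`.
#' @export
multistart_search <- function(peptide, slab = NULL,
                              config = stunbh_config(),
                              params = default_forcefield()) {
  if (is.character(peptide) || inherits(peptide, "peptide_sequence"))
    peptide <- build_conformation(peptide)
  set.seed(config$seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, config$n_starts)
  results <- vector("list", config$n_starts)
  failures <- list()
  for (s in seq_len(config$n_starts)) {
    set.seed(start_seeds[s])
    res <- tryCatch({
      start <- if (!is.null(slab)) place_peptide(peptide, slab, config)
      else {
        st <- peptide
        st$coords <- st$coords +
          0.3 * matrix(stats::rnorm(length(st$coords)), ncol = 3)
        st
      }
      cfg_s <- config
      cfg_s$seed <- start_seeds[s]
      stunbh_iterate(start, cfg_s, params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(start = s,
                                                message = conditionMessage(res))
    } else results[[s]] <- res
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all starts failed", call. = FALSE)
  energies <- vapply(results[ok], `[[`, numeric(1), "best_energy")
  ord <- order(energies)
  minima <- list()
  for (k in ord) {
    r <- results[ok][[k]]
    dup <- FALSE
    for (mi in seq_along(minima)) {
      m <- minima[[mi]]
      if (abs(m$e_be - r$best_energy) < config$dedup_de) {
        c1 <- m$system$coords[!m$system$atoms$fixed, , drop = FALSE]
        c2 <- r$best_state$coords[!r$best_state$atoms$fixed, , drop = FALSE]
        if (nrow(c1) == nrow(c2) &&
            rmsd_superposed(c1, c2) < config$dedup_rmsd) {
          minima[[mi]]$multiplicity <- m$multiplicity + 1L
          dup <- TRUE
          break
        }
      }
    }
    if (!dup)
      minima[[length(minima) + 1L]] <- list(system = r$best_state,
                                            e_be = r$best_energy,
                                            multiplicity = 1L)
  }
  structure(list(
    minima = minima,
    best_per_start = data.frame(start = which(ok),
                                seed = start_seeds[ok],
                                e_be = energies),
    planned_iterations = planned_iterations(config),
    completed_iterations = sum(ok) * config$iterations,
    accept_rate = mean(vapply(results[ok], `[[`, numeric(1), "accept_rate")),
    failures = failures,
    seed = config$seed
  ), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> ", length(x$minima), " distinct minima from ",
      nrow(x$best_per_start), " starts (",
      x$completed_iterations, "/", x$planned_iterations,
      " iterations, mean acceptance ",
      sprintf("%.2f", x$accept_rate), ")\n", sep = "")
  if (length(x$minima)) {
    e <- vapply(x$minima, `[[`, numeric(1), "e_be")
    m <- vapply(x$minima, `[[`, integer(1), "multiplicity")
    for (i in seq_len(min(5, length(e))))
      cat(sprintf("  #%d  E_BE = %10.4f kcal/mol  (x%d)\n", i, e[i], m[i]))
  }
  invisible(x)
}
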