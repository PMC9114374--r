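# Stage-scheduled simulation driver: orchestrates the implicit stepping,
# periodic topology refresh (labeling, tip detection and tracking,
# activation zones, intersection guard, domain extension), axon
# differentiation at the stage-3 transition, and cue-guided growth.

#' Run a staged neuron-growth simulation
#'
#' Executes the four growth stages under the iteration schedule in
#' `config$params$schedule`:
#' stage 1 (lamellipodia formation) drives the whole interface with the
#' undercooling-limited driving force; stages 2-4 restrict the driving
#' force to 6 x 6 energy activation zones at detected neurite tips, with
#' global assembly/disassembly rates in stage 2 (uniform outgrowth),
#' per-neurite rates after geodesic longest-neurite axon selection at the
#' start of stage 3 (axon differentiation), and growth-permissive rates
#' plus fresh extracellular cues for every tip in stage 4 (dendrite
#' formation). The domain is extended by 10 points per flagged side when
#' a tip nears the boundary. Fully reproducible from
#' `config$params$rng_seed`.
#'
#' @param config list with `nu`, `nv` (grid size), `centers` (k x 2 soma
#'   centers, lattice coordinates) and `params` (a [neuron_params()]);
#'   see [reference_configs()].
#' @param iterations total iterations to run (default: the end of the
#'   schedule).
#' @param settings a [solver_settings()] object.
#' @param snapshot_every snapshot cadence in iterations (default: ~10
#'   snapshots over the run).
#' @param progress print a line at each snapshot.
#' @return An object of class `neuron_growth_sim`: final `state`, `grid`,
#'   `params`, `snapshots`, `events` (list; serialize with
#'   [event_log_lines()]), `lengths_log` (per-neurite geodesic length at
#'   each topology refresh), `registry` (per-neurite bookkeeping) and
#'   Newton iteration statistics.
#' @export
run_simulation <- function(config, iterations = NULL,
                           settings = solver_settings(),
                           snapshot_every = NULL, progress = FALSE) {
  params <- config$params
  total <- if (is.null(iterations)) params$schedule[4] else as.integer(iterations)
  if (is.null(snapshot_every)) snapshot_every <- max(1L, total %/% 10L)
  grid <- build_collocation_grid(config$nu, config$nv)
  centers_phys <- matrix(as.numeric(config$centers), ncol = 2)
  # config centers are lattice coordinates; convert via the Greville points
  centers_phys <- cbind(grid$gu[pmin(pmax(round(centers_phys[, 1]), 1), grid$nu)],
                        grid$gv[pmin(pmax(round(centers_phys[, 2]), 1), grid$nv)])
  state <- initialize_state(params, centers_phys, grid)
  set.seed(params$rng_seed)

  env <- new.env(parent = emptyenv())
  env$registry <- data.frame(
    neurite_id = integer(0), neuron_id = integer(0),
    ix = integer(0), iy = integer(0), geodesic = numeric(0),
    r = numeric(0), s = numeric(0), born = integer(0),
    has_cue = logical(0), cue_x = numeric(0), cue_y = numeric(0))
  env$positions <- list()       # per-neurite recent tip positions
  env$events <- list()
  env$lengths <- list()
  env$conflict <- NULL
  env$axon <- NA_integer_
  env$newton_iters <- integer(total)
  env$newton_resid <- numeric(total)

  ev <- function(...) env$events[[length(env$events) + 1L]] <- list(...)
  ev(iteration = 0L, type = "init", nu = grid$nu, nv = grid$nv,
     neurons = nrow(centers_phys), seed = params$rng_seed)

  refresh <- function(state, grid, it, stage) {
    cl <- .centers_lattice(state, grid)
    tips <- detect_tips(state$phi, cl, params$r0,
                        threshold = params$phi_threshold,
                        exclusion = tip_exclusion_radius(params),
                        min_separation = params$tip_min_separation)
    rim <- attr(tips, "rim_level")
    reg <- env$registry
    matched_new <- rep(NA_integer_, nrow(tips))
    if (nrow(tips) && nrow(reg)) {
      for (t in seq_len(nrow(tips))) {
        d <- sqrt((reg$ix - tips$ix[t])^2 + (reg$iy - tips$iy[t])^2)
        d[reg$neuron_id != tips$neuron_id[t]] <- Inf
        if (length(d) && min(d) <= params$tip_match_radius) {
          matched_new[t] <- which.min(d)
        }
      }
      # one registry entry per detected tip: keep the nearest
      dup <- duplicated(matched_new, incomparables = NA)
      matched_new[dup] <- NA_integer_
    }
    for (t in seq_len(nrow(tips))) {
      m <- matched_new[t]
      if (!is.na(m)) {
        # only growth-capable neurites track the moving front: an
        # inhibited (r = 0) entry cannot advance, and letting it claim a
        # nearby moving tip would transfer the grower's identity
        if (reg$r[m] > 0) {
          reg$ix[m] <- tips$ix[t]; reg$iy[m] <- tips$iy[t]
          reg$geodesic[m] <- max(reg$geodesic[m], tips$geodesic[t])
          id <- reg$neurite_id[m]
          env$positions[[as.character(id)]] <-
            rbind(env$positions[[as.character(id)]], c(tips$ix[t], tips$iy[t]))
        }
      } else {
        # once a neuron has growth cones, a new one must protrude above
        # the rim level: shallow ripples of a broad front are not
        # neurites
        has_any <- any(reg$neuron_id == tips$neuron_id[t])
        rim_n <- rim[tips$neuron_id[t]]
        if (has_any && is.finite(rim_n) &&
            tips$geodesic[t] < rim_n + params$tip_prominence) next
        id <- if (nrow(reg)) max(reg$neurite_id) + 1L else 1L
        # newborn neurites grow with the global rates except during the
        # axon-differentiation stage, where non-axon growth is suppressed
        rr <- if (stage == 3L) 0 else params$r_g
        reg <- rbind(reg, data.frame(
          neurite_id = id, neuron_id = tips$neuron_id[t],
          ix = tips$ix[t], iy = tips$iy[t], geodesic = tips$geodesic[t],
          r = rr, s = params$s_g, born = it, has_cue = FALSE,
          cue_x = NA_real_, cue_y = NA_real_))
        env$positions[[as.character(id)]] <-
          matrix(c(tips$ix[t], tips$iy[t]), 1, 2)
        ev(iteration = it, type = "tip_birth", neurite = id,
           neuron = tips$neuron_id[t], ix = tips$ix[t], iy = tips$iy[t])
      }
    }
    env$registry <- reg
    if (nrow(reg)) {
      env$lengths[[length(env$lengths) + 1L]] <- data.frame(
        iteration = it, neurite_id = reg$neurite_id,
        geodesic = reg$geodesic)
    }
    al <- arm_labels(state$phi, cl, params$r0, params$phi_threshold)
    env$conflict <- .conflict_mask(al$arms, al$neuron)
    state$neuron_labels <- label_components(state$phi,
                                            params$phi_threshold, cl)
    state
  }

  active_tips <- function(state, grid) {
    reg <- env$registry
    if (!nrow(reg)) return(reg)
    zci <- reg$ix; zcj <- reg$iy
    for (k in seq_len(nrow(reg))) {
      if (isTRUE(reg$has_cue[k])) {
        u <- c(reg$cue_x[k] - reg$ix[k], reg$cue_y[k] - reg$iy[k])
        nu_ <- sqrt(sum(u^2))
        if (nu_ > 1e-9) {
          zci[k] <- as.integer(round(reg$ix[k] + params$zone_shift * u[1] / nu_))
          zcj[k] <- as.integer(round(reg$iy[k] + params$zone_shift * u[2] / nu_))
        }
      }
    }
    reg$zone_ci <- pmin(pmax(zci, 1L), grid$nu)
    reg$zone_cj <- pmin(pmax(zcj, 1L), grid$nv)
    reg
  }

  heading_of <- function(state, grid, id) {
    hist <- env$positions[[as.character(id)]]
    k <- env$registry$neurite_id == id
    if (!is.null(hist) && nrow(hist) >= 2) {
      i0 <- max(1L, nrow(hist) - params$heading_window + 1L)
      h <- hist[nrow(hist), ] - hist[i0, ]
      if (sum(h^2) > 1e-12) return(h / sqrt(sum(h^2)))
    }
    cl <- .centers_lattice(state, grid)
    ctr <- cl[env$registry$neuron_id[k], ]
    h <- c(env$registry$ix[k] - ctr[1], env$registry$iy[k] - ctr[2])
    h / max(sqrt(sum(h^2)), 1e-9)
  }

  place_cue_for <- function(state, grid, id, it) {
    k <- which(env$registry$neurite_id == id)
    cp <- place_extracellular_cue(
      c(env$registry$ix[k], env$registry$iy[k]),
      heading_of(state, grid, id), params)
    env$registry$has_cue[k] <- TRUE
    env$registry$cue_x[k] <- cp$cue[1]
    env$registry$cue_y[k] <- cp$cue[2]
    ev(iteration = it, type = "cue_placed", neurite = id,
       angle = round(cp$angle, 4), cue_x = round(cp$cue[1], 3),
       cue_y = round(cp$cue[2], 3))
  }

  snapshots <- list(.make_snapshot(state, grid, env, 0L))
  state <- refresh(state, grid, 0L, 1L)
  sched <- params$schedule
  stage_prev <- 1L

  for (it in seq_len(total)) {
    stage <- stage_of_iteration(it, sched)
    if (stage != stage_prev) {
      ev(iteration = it, type = "stage", stage = stage)
      if (stage == 3L) {
        state <- refresh(state, grid, it, stage)
        reg <- env$registry
        if (nrow(reg)) {
          sel <- select_axon(reg, params)
          env$axon <- sel$axon
          reg$r <- sel$rates$r[match(reg$neurite_id, sel$rates$neurite_id)]
          reg$s <- sel$rates$s[match(reg$neurite_id, sel$rates$neurite_id)]
          env$registry <- reg
          ev(iteration = it, type = "axon_selected", neurite = sel$axon,
             geodesic = round(reg$geodesic[reg$neurite_id == sel$axon], 3))
          place_cue_for(state, grid, sel$axon, it)
        }
      }
      if (stage == 4L) {
        reg <- env$registry
        if (nrow(reg)) {
          reg$r <- params$r_g
          env$registry <- reg
          for (id in reg$neurite_id) {
            if (!reg$has_cue[reg$neurite_id == id]) {
              place_cue_for(state, grid, id, it)
            }
          }
        }
      }
      stage_prev <- stage
    }

    if (it %% params$retip_every == 1L || params$retip_every == 1L) {
      state <- refresh(state, grid, it, stage)
      ext <- extend_domain(state, grid, env$registry, params)
      if (any(ext$extended)) {
        shift <- EXTEND_WIDTH * c(ext$extended[["left"]],
                                  ext$extended[["bottom"]])
        state <- ext$state; grid <- ext$grid
        if (any(shift > 0)) {
          env$registry$ix <- env$registry$ix + shift[1]
          env$registry$iy <- env$registry$iy + shift[2]
          env$registry$cue_x <- env$registry$cue_x + shift[1]
          env$registry$cue_y <- env$registry$cue_y + shift[2]
          env$positions <- lapply(env$positions, function(m)
            sweep(m, 2, -shift))
        }
        ev(iteration = it, type = "extension",
           sides = paste(names(ext$extended)[ext$extended], collapse = "+"),
           nu = grid$nu, nv = grid$nv,
           transfer_error = ext$transfer_error,
           components_before = ext$components_before,
           components_after = ext$components_after)
        state <- refresh(state, grid, it, stage)
      }
    }

    state$E_field <- if (stage == 1L) {
      compute_driving_force_global(state, params)
    } else {
      compute_driving_force(state, active_tips(state, grid), params)
    }

    phi_prev <- state$phi
    state <- implicit_euler_step(state, grid, params, settings)
    if (!is.null(env$conflict) && any(env$conflict)) {
      sup <- env$conflict & (state$phi > phi_prev)
      state$phi[sup] <- phi_prev[sup]
    }
    state$stage <- stage
    env$newton_iters[it] <- state$last_newton$iterations
    env$newton_resid[it] <- state$last_newton$residual

    if (it %% snapshot_every == 0L || it == total) {
      snapshots[[length(snapshots) + 1L]] <- .make_snapshot(state, grid, env, it)
      if (progress) {
        message(sprintf("iter %d stage %d tips %d newton %d resid %.2e",
                        it, stage, nrow(env$registry),
                        env$newton_iters[it], env$newton_resid[it]))
      }
    }
  }

  structure(list(
    state = state, grid = grid, params = params,
    centers = centers_phys,
    snapshots = snapshots, events = env$events,
    lengths_log = if (length(env$lengths)) do.call(rbind, env$lengths)
                  else data.frame(iteration = integer(0),
                                  neurite_id = integer(0),
                                  geodesic = numeric(0)),
    registry = env$registry, axon = env$axon,
    newton_iters = env$newton_iters, newton_resid = env$newton_resid),
    class = "neuron_growth_sim")
}

.make_snapshot <- function(state, grid, env, it) {
  list(iteration = it, stage = state$stage,
       nu = grid$nu, nv = grid$nv, degree = grid$degree,
       spacing = grid$spacing, origin = grid$origin,
       phi = state$phi, c_tub = state$c_tub,
       n_tips = nrow(env$registry),
       lengths = if (nrow(env$registry))
         stats::setNames(env$registry$geodesic,
                         env$registry$neurite_id) else numeric(0))
}

#' @export
print.neuron_growth_sim <- function(x, ...) {
  cat("Neuron growth simulation:", x$state$iteration, "iterations | stage",
      x$state$stage, "| grid", x$grid$nu, "x", x$grid$nv, "\n")
  cat("  neurites:", nrow(x$registry),
      "| axon:", if (is.na(x$axon)) "(none)" else x$axon,
      "| max Newton residual:", format(max(x$newton_resid), digits = 3),
      "\n")
  invisible(x)
}

#' Serialize the simulation event log as JSON lines
#'
#' One JSON object per event (initialization, stage transitions, tip
#' births, axon selection, cue placements, domain extensions). Two runs
#' with identical configuration and seed produce identical lines.
#'
#' @param sim a `neuron_growth_sim`.
#' @return character vector of JSON lines.
#' @export
event_log_lines <- function(sim) {
  vapply(sim$events, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA)),
    character(1))
}

#' Write the event log to a JSON-lines file
#' @param sim a `neuron_growth_sim`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(sim, path) {
  writeLines(event_log_lines(sim), path)
  invisible(path)
}
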