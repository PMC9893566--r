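# Property-guided search in the latent space: minimize
# L_v0(z) = |v0 - f_R(z)|^p over R_n with the regressor weights frozen.
# Algorithm A is plain gradient descent; Algorithm B periodically decodes the
# current point to a molecule and re-encodes its mean, so the search stays on
# embeddings that correspond to actual molecules.

#' Property target specification
#'
#' @param name Property name (e.g. "homo").
#' @param units Units of the property (e.g. "eV", or surrogate units).
#' @param target_value The desired property value v0.
#' @param p_norm Exponent p >= 1 of the loss |v0 - f_R(z)|^p (default 1,
#'   matching the MAE reporting; at p = 1 the subgradient at the kink is 0).
#' @return A `jtprop_property_spec`.
#' @export
property_spec <- function(name = "homo", units = "eV", target_value,
                          p_norm = 1) {
  stopifnot(is.numeric(target_value), length(target_value) == 1L, p_norm >= 1)
  structure(list(name = name, units = units, target_value = target_value,
                 p_norm = p_norm), class = "jtprop_property_spec")
}

#' Latent-optimization configuration
#'
#' @param target A `jtprop_property_spec` (or a bare numeric target value).
#' @param lr Gradient-descent learning rate.
#' @param max_iterations Iteration budget (default 100).
#' @param tolerance Convergence tolerance on the loss.
#' @param reencode_period Algorithm B: decode/re-encode every this many
#'   gradient steps (also at termination).
#' @param noise_scale Standard deviation multiplier of the Gaussian noise
#'   added by the CTV/CHV initializations (default 1; the noise itself is
#'   N(0, I)).
#' @param seed RNG seed for every stochastic element.
#' @return A `jtprop_opt_config`.
#' @export
opt_config <- function(target, lr = 0.05, max_iterations = 100L,
                       tolerance = 1e-3, reencode_period = 10L,
                       noise_scale = 1, seed = 1L) {
  if (is.numeric(target)) target <- property_spec(target_value = target)
  stopifnot(inherits(target, "jtprop_property_spec"),
            max_iterations >= 1L, tolerance > 0, reencode_period >= 1L,
            noise_scale >= 0)
  structure(list(target = target, lr = lr,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 reencode_period = as.integer(reencode_period),
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "jtprop_opt_config")
}

#' Property loss at a latent point
#'
#' `|v0 - f_R(z)|^p` with the configured norm exponent.
#'
#' @param z Numeric latent vector.
#' @param spec A `jtprop_property_spec`.
#' @param model A `jtprop_model` (provides the frozen regressor f_R).
#' @return Nonnegative scalar.
#' @export
property_loss <- function(z, spec, model) {
  abs(spec$target_value - predict_property(z, model))^spec$p_norm
}

# Loss and gradient in one reverse pass.
property_loss_grad <- function(z, spec, model) {
  P <- lapply(model$params, ag_input)
  zn <- ag_input(matrix(as.numeric(z), 1L), requires = TRUE)
  out <- regressor_forward(zn, P, model$reg_stats)$out
  diff <- ag_abs(ag_sub(ag_input(matrix(spec$target_value, 1L, 1L)), out))
  loss <- ag_powc(diff, spec$p_norm)
  ag_backward(loss)
  list(loss = loss$value[1L], grad = as.numeric(zn$grad),
       predicted = out$value[1L])
}

new_trace_record <- function(iteration, z, predicted, loss,
                             smiles = NA_character_) {
  tibble::tibble(iteration = iteration, z = list(as.numeric(z)),
                 predicted = predicted, loss = loss, smiles = smiles)
}

finish_trace <- function(records, status) {
  tr <- dplyr::bind_rows(records)
  attr(tr, "status") <- status
  class(tr) <- c("jtprop_trace", class(tr))
  tr
}

#' Algorithm A: gradient descent in the latent space
#'
#' Iterates `z <- z - lr * grad L_v0(z)` with the regressor weights frozen
#' until the loss drops to the tolerance or the iteration budget is
#' exhausted. The trace records every visited point. A non-finite gradient
#' aborts with the diagnostic trace attached to the error.
#'
#' @param z0 Numeric starting vector.
#' @param cfg A `jtprop_opt_config`.
#' @param model A `jtprop_model`.
#' @return List with `z` (the final point) and `trace` (a `jtprop_trace`
#'   tibble; `attr(trace, "status")` is "converged" or "budget-exhausted").
#' @export
optimize_A <- function(z0, cfg, model) {
  stopifnot(inherits(cfg, "jtprop_opt_config"))
  z <- as.numeric(z0)
  records <- list()
  status <- "budget-exhausted"
  for (it in seq_len(cfg$max_iterations)) {
    lg <- property_loss_grad(z, cfg$target, model)
    records[[length(records) + 1L]] <-
      new_trace_record(it - 1L, z, lg$predicted, lg$loss)
    if (lg$loss <= cfg$tolerance) {
      status <- "converged"
      break
    }
    if (!all(is.finite(lg$grad))) {
      e <- simpleError("non-finite gradient during latent optimization")
      e$trace <- finish_trace(records, "aborted")
      stop(e)
    }
    z <- z - cfg$lr * lg$grad
  }
  list(z = z, trace = finish_trace(records, status))
}

#' Algorithm B: gradient descent with decode/re-encode projection
#'
#' Runs the same gradient steps as Algorithm A but, every `reencode_period`
#' iterations and at termination, decodes the current point to a molecule,
#' re-encodes it to its mean embedding, and continues from that mean. The
#' returned molecule is the visited (decoded) molecule whose predicted
#' property is closest to the target — projection can worsen the loss, so the
#' best visited molecule, not the last iterate, is returned. Decode failures
#' mid-run are logged and skipped; the final answer is always a decodable,
#' chemically valid molecule.
#'
#' @param z0 Numeric starting vector.
#' @param cfg A `jtprop_opt_config`.
#' @param model A `jtprop_model`.
#' @return List with `molecule` (a `jtprop_molecule`), `predicted` (its
#'   predicted property at the re-encoded mean), and `trace`.
#' @export
optimize_B <- function(z0, cfg, model) {
  stopifnot(inherits(cfg, "jtprop_opt_config"))
  z <- as.numeric(z0)
  records <- list()
  best <- NULL
  status <- "budget-exhausted"

  project <- function(z, it) {
    m <- tryCatch(decode(z, model), error = function(e) {
      message(sprintf("decode failed at iteration %d: %s; skipping projection",
                      it, conditionMessage(e)))
      NULL
    })
    if (is.null(m)) return(NULL)
    zm <- encode(m, model)$z
    pred <- predict_property(zm, model)
    records[[length(records) + 1L]] <<-
      new_trace_record(it, zm, pred,
                       abs(cfg$target$target_value - pred)^cfg$target$p_norm,
                       smiles = m$smiles)
    gap <- abs(pred - cfg$target$target_value)
    if (is.null(best) || gap < best$gap) {
      best <<- list(molecule = m, predicted = pred, gap = gap, z = zm)
    }
    zm
  }

  lg <- property_loss_grad(z, cfg$target, model)
  records[[length(records) + 1L]] <- new_trace_record(0L, z, lg$predicted,
                                                      lg$loss)
  if (lg$loss <= cfg$tolerance) {
    project(z, 0L)
    return(list(molecule = best$molecule, predicted = best$predicted,
                trace = finish_trace(records, "converged")))
  }
  for (it in seq_len(cfg$max_iterations)) {
    if (!all(is.finite(lg$grad))) {
      e <- simpleError("non-finite gradient during latent optimization")
      e$trace <- finish_trace(records, "aborted")
      stop(e)
    }
    z <- z - cfg$lr * lg$grad
    if (it %% cfg$reencode_period == 0L) {
      zp <- project(z, it)
      if (!is.null(zp)) z <- zp
    }
    lg <- property_loss_grad(z, cfg$target, model)
    records[[length(records) + 1L]] <- new_trace_record(it, z, lg$predicted,
                                                        lg$loss)
    if (lg$loss <= cfg$tolerance) {
      status <- "converged"
      break
    }
  }
  project(z, cfg$max_iterations + 1L)  # terminal projection
  if (is.null(best)) {
    stop("no decodable molecule visited during optimization", call. = FALSE)
  }
  list(molecule = best$molecule, predicted = best$predicted,
       trace = finish_trace(records, status))
}

# --- initializations ---------------------------------------------------------

#' Latent initializations for the guided search
#'
#' * `init_gaussian`: draw from N(0, I) in the stacked latent space.
#' * `init_ctv`: the mean embedding of the training molecule whose property
#'   value is closest to the target (ties to the lowest index), plus
#'   N(0, I) noise scaled by `noise_scale`.
#' * `init_chv`: the mean embedding of the training molecule closest in L2
#'   distance to the embedding of a given seed molecule, plus the same noise.
#'
#' @param dim Latent dimension (gaussian).
#' @param cfg A `jtprop_opt_config` (provides seed, noise scale, target).
#' @return Numeric vector.
#' @rdname initializations
#' @export
init_gaussian <- function(dim, cfg) {
  stopifnot(dim >= 1L)
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(cfg$seed)
  stats::rnorm(dim)
}

#' @param train_set A data frame with list-column `latent` (mean embeddings)
#'   and column `value` (property values) for the regression training set.
#' @rdname initializations
#' @export
init_ctv <- function(train_set, cfg) {
  if (is.null(train_set) || nrow(train_set) == 0L) {
    stop("CTV initialization needs a non-empty training set", call. = FALSE)
  }
  i <- which.min(abs(train_set$value - cfg$target$target_value))
  base <- as.numeric(train_set$latent[[i]])
  add_init_noise(base, cfg)
}

#' @param m_int Seed molecule (`jtprop_molecule` or SMILES) whose latent
#'   neighborhood is searched (chv).
#' @param model A `jtprop_model` (chv; used to embed `m_int`).
#' @rdname initializations
#' @export
init_chv <- function(m_int, train_set, model, cfg) {
  if (is.null(train_set) || nrow(train_set) == 0L) {
    stop("CHV initialization needs a non-empty training set", call. = FALSE)
  }
  zq <- encode(m_int, model)$z
  d2 <- vapply(train_set$latent, function(zi) sum((as.numeric(zi) - zq)^2),
               numeric(1))
  base <- as.numeric(train_set$latent[[which.min(d2)]])
  add_init_noise(base, cfg)
}

add_init_noise <- function(base, cfg) {
  if (cfg$noise_scale == 0) return(base)
  old <- preserve_rng()
  on.exit(restore_rng(old))
  set.seed(cfg$seed)
  base + cfg$noise_scale * stats::rnorm(length(base))
}

#' Guided recovery rate
#'
#' For every test molecule: set the target to its own property value,
#' initialize per `init_mode`, run the chosen search algorithm, decode, and
#' count exact canonical-SMILES matches. Per-molecule failures count as
#' non-recovery.
#'
#' @param test_set Data frame with columns `smiles` and `value`.
#' @param model A `jtprop_model`.
#' @param init_mode One of "gaussian", "ctv", "chv".
#' @param algorithm "A" or "B".
#' @param cfg A `jtprop_opt_config` (its target value is overridden per
#'   molecule).
#' @param train_set Latent/value table for ctv/chv (see [init_ctv()]).
#' @return Percentage in \[0, 100\].
#' @export
guided_recovery_rate <- function(test_set, model, init_mode = c("chv", "ctv", "gaussian"),
                                 algorithm = c("B", "A"), cfg,
                                 train_set = NULL) {
  init_mode <- match.arg(init_mode)
  algorithm <- match.arg(algorithm)
  stopifnot(nrow(test_set) >= 1L)
  hits <- vapply(seq_len(nrow(test_set)), function(i) {
    smi <- test_set$smiles[i]
    cfg_i <- cfg
    cfg_i$target$target_value <- test_set$value[i]
    cfg_i$seed <- cfg$seed + i
    ok <- tryCatch({
      z0 <- switch(init_mode,
                   gaussian = init_gaussian(2L * model$enc_cfg$latent_dim, cfg_i),
                   ctv = init_ctv(train_set, cfg_i),
                   chv = init_chv(smi, train_set, model, cfg_i))
      out <- if (algorithm == "A") {
        res <- optimize_A(z0, cfg_i, model)
        decode(res$z, model)
      } else {
        optimize_B(z0, cfg_i, model)$molecule
      }
      identical(out$smiles, canonical_smiles(smi))
    }, error = function(e) FALSE)
    ok
  }, logical(1))
  100 * mean(hits)
}
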