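#' Kinetic parameters for the continuous translation of a logical model
#'
#' Each species carries a production rate `beta` (concentration/time), a
#' degradation rate `gamma` (1/time) and an initial concentration `x0`
#' (mM/L); each interaction carries a Hill threshold `theta`
#' (concentration at half-activation) and Hill coefficient `h`
#' (dimensionless steepness). Scalars are recycled across species/edges;
#' named vectors override per species (`beta = c(ERK = 0.2)`).
#'
#' @param net a `brn`.
#' @param beta,gamma,x0 per-species values (scalar or named).
#' @param theta,h per-edge values (scalar, or named by `"source->target"`).
#' @return an object of class `ode_kinetics`: tibbles `species` (name,
#'   beta, gamma, x0) and `edges` (source, target, theta, h).
#' @export
ode_kinetics <- function(net, beta = 1, gamma = 1, x0 = 0,
                         theta = 0.5, h = 8) {
  stopifnot(inherits(net, "brn"))
  nm <- net$entities$name
  fill <- function(x, keys, what) {
    out <- rep(unname(x)[1], length(keys))
    names(out) <- keys
    if (!is.null(names(x))) {
      bad <- setdiff(names(x)[nzchar(names(x))], keys)
      if (length(bad)) stop("unknown ", what, ": ",
                            paste(bad, collapse = ", "), call. = FALSE)
      out[names(x)[nzchar(names(x))]] <- x[nzchar(names(x))]
    }
    out
  }
  species <- tibble::tibble(name = nm,
                            beta = fill(beta, nm, "species"),
                            gamma = fill(gamma, nm, "species"),
                            x0 = fill(x0, nm, "species"))
  ekey <- paste0(net$interactions$source, "->", net$interactions$target)
  edges <- tibble::tibble(source = net$interactions$source,
                          target = net$interactions$target,
                          theta = fill(theta, ekey, "edge")[ekey],
                          h = fill(h, ekey, "edge")[ekey])
  if (any(species$beta < 0) || any(species$gamma <= 0) || any(species$x0 < 0) ||
      any(edges$theta <= 0) || any(edges$h < 1)) {
    stop("kinetics out of range: need beta >= 0, gamma > 0, x0 >= 0, ",
         "theta > 0, h >= 1", call. = FALSE)
  }
  structure(list(species = species, edges = edges), class = "ode_kinetics")
}

#' Read kinetics from a YAML file
#'
#' Layout: top-level `defaults` (beta, gamma, x0, theta, h) plus optional
#' `species:` (per-name overrides) and `edges:` (list of `{source, target,
#' theta, h}` overrides).
#'
#' @param path YAML file.
#' @param net the `brn` the kinetics belong to.
#' @return an `ode_kinetics`.
#' @export
read_kinetics <- function(path, net) {
  doc <- yaml::read_yaml(path)
  dft <- doc$defaults %||% list()
  take <- function(field, default) {
    base <- as.numeric(dft[[field]] %||% default)
    ov <- doc$species %||% list()
    named <- vapply(ov, function(s) as.numeric(s[[field]] %||% base),
                    numeric(1))
    if (length(named)) c(base, stats::setNames(named, names(ov))) else base
  }
  beta <- take("beta", 1); gamma <- take("gamma", 1); x0 <- take("x0", 0)
  theta <- dft$theta %||% 0.5; h <- dft$h %||% 8
  kin <- ode_kinetics(net, beta = beta, gamma = gamma, x0 = x0,
                      theta = theta, h = h)
  for (e in doc$edges %||% list()) {
    i <- which(kin$edges$source == e$source & kin$edges$target == e$target)
    if (!length(i)) stop("kinetics file names unknown edge ", e$source,
                         " -> ", e$target, call. = FALSE)
    if (!is.null(e$theta)) kin$edges$theta[i] <- as.numeric(e$theta)
    if (!is.null(e$h)) kin$edges$h[i] <- as.numeric(e$h)
  }
  kin
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hill <- function(x, theta, h) {
  x <- pmax(x, 0)
  x^h / (x^h + theta^h)
}

#' Translate a logical model into an ODE system
#'
#' Each species obeys `dx/dt = beta * f(x) - gamma * x` with a bounded
#' regulation function `f` in `[0, 1]`:
#'
#' * `regulation = "table"` (default): the multilinear interpolation of the
#'   logical K table. Each regulator u contributes a continuous "resource
#'   weight" — the Hill function `H(x_u; theta, h)` for an activator, `1 -
#'   H` for an inhibitor — and `f` is the expectation of `K/max_level` over
#'   resource subsets weighted by those terms. Steep Hill functions make
#'   the continuous steady states mirror the logical model's stable
#'   states, so the discrete and continuous analyses can be compared.
#' * `regulation = "product"`: signs only; `f` is the product over
#'   regulators of `H` (activators) and `1 - H` (inhibitors), ignoring the
#'   K table.
#'
#' Unregulated species have `f = 1`.
#'
#' @param model a `brn_model` (a plain `brn` is accepted for
#'   `regulation = "product"`).
#' @param kinetics an `ode_kinetics`.
#' @param regulation `"table"` or `"product"`.
#' @return an object of class `ode_system`.
#' @export
brn_to_ode <- function(model, kinetics, regulation = c("table", "product")) {
  regulation <- match.arg(regulation)
  net <- if (inherits(model, "brn_model")) model$network else model
  stopifnot(inherits(net, "brn"), inherits(kinetics, "ode_kinetics"))
  if (regulation == "table" && !inherits(model, "brn_model")) {
    stop("`regulation = \"table\"` needs a brn_model (the K table)",
         call. = FALSE)
  }
  if (!setequal(kinetics$species$name, net$entities$name)) {
    stop("kinetics do not cover the network's species", call. = FALSE)
  }
  nm <- net$entities$name
  sp <- kinetics$species[match(nm, kinetics$species$name), ]
  regs <- lapply(nm, function(v) {
    rg <- regulators(net, v)
    ek <- match(paste0(rg$source, "->", v),
                paste0(kinetics$edges$source, "->", kinetics$edges$target))
    rg$theta <- kinetics$edges$theta[ek]
    rg$h <- kinetics$edges$h[ek]
    rg
  })
  names(regs) <- nm
  ml <- net$entities$max_level
  kmap <- if (inherits(model, "brn_model")) model$parameters$kmap

  freg <- function(x) {
    out <- numeric(length(nm))
    for (j in seq_along(nm)) {
      rg <- regs[[j]]
      k <- nrow(rg)
      if (k == 0L) {
        out[j] <- if (regulation == "table") kmap[[j]][1L] / ml[j] else 1
        next
      }
      p <- hill(x[rg$source], rg$theta, rg$h)
      p[rg$sign == "-"] <- 1 - p[rg$sign == "-"]  # weight of being a resource
      if (regulation == "product") {
        out[j] <- prod(p)
      } else {
        f <- 0
        for (m in 0:(2^k - 1)) {
          inset <- bitwAnd(m, 2^(seq_len(k) - 1)) > 0
          w <- prod(ifelse(inset, p, 1 - p))
          f <- f + w * kmap[[j]][m + 1L] / ml[j]
        }
        out[j] <- f
      }
    }
    out
  }

  rhs <- function(t, x, parms) {
    list(sp$beta * freg(x) - sp$gamma * pmax(x, 0))
  }

  structure(list(network = net, species = nm, kinetics = kinetics,
                 model = if (inherits(model, "brn_model")) model,
                 regulation = regulation, rhs = rhs, f = freg,
                 beta = stats::setNames(sp$beta, nm),
                 gamma = stats::setNames(sp$gamma, nm),
                 x0 = stats::setNames(sp$x0, nm)),
            class = "ode_system")
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("<ode_system> %d species, %s regulation\n",
              length(x$species), x$regulation))
  invisible(x)
}

#' Simulate an ODE system
#'
#' Adaptive stiff-capable integration (`deSolve::ode`, lsoda); output
#' sampled on a uniform grid; tiny negative excursions are clipped to zero.
#'
#' @param system an `ode_system`.
#' @param t_end end time (> 0), in abstract time units.
#' @param n_points number of output samples (including t = 0).
#' @param x0 optional initial concentrations (default: the kinetics' x0).
#' @param ... passed to [deSolve::ode()].
#' @return an `ode_trajectory`: a tibble (time, species, concentration)
#'   with the wide solution matrix in `attr(, "matrix")`.
#' @export
simulate_ode <- function(system, t_end, n_points = 201, x0 = NULL, ...) {
  stopifnot(inherits(system, "ode_system"), t_end > 0)
  y0 <- if (is.null(x0)) system$x0 else {
    y <- system$x0
    y[names(x0)] <- x0
    y
  }
  times <- seq(0, t_end, length.out = n_points)
  sol <- deSolve::ode(y = y0, times = times, func = system$rhs, parms = NULL,
                      ...)
  mat <- unclass(sol)
  mat[, -1][mat[, -1] < 0] <- 0
  long <- tidyr::pivot_longer(tibble::as_tibble(as.data.frame(mat)),
                              -"time", names_to = "species",
                              values_to = "concentration")
  long$species <- factor(long$species, levels = system$species)
  structure(long, matrix = mat, class = c("ode_trajectory", class(long)))
}

#' Equilibrium concentrations of an ODE system
#'
#' Long-time integration followed by damped-Newton refinement with a
#' finite-difference Jacobian; the returned point satisfies
#' `max |dx/dt| <= tol`.
#'
#' @param system an `ode_system`.
#' @param x_start starting concentrations (default: the kinetics' x0).
#' @param tol residual bound (default 1e-8).
#' @param t_probe integration horizon used to approach the attractor.
#' @param max_iter Newton iteration cap.
#' @return a named numeric vector of concentrations with attribute
#'   `residual`.
#' @export
ode_equilibrium <- function(system, x_start = NULL, tol = 1e-8,
                            t_probe = 500, max_iter = 50) {
  stopifnot(inherits(system, "ode_system"), tol > 0)
  y <- if (is.null(x_start)) system$x0 else {
    y0 <- system$x0
    y0[names(x_start)] <- x_start
    y0
  }
  sol <- deSolve::ode(y = y, times = c(0, t_probe), func = system$rhs,
                      parms = NULL)
  y <- pmax(sol[nrow(sol), -1], 0)
  g <- function(x) system$rhs(0, x, NULL)[[1]]
  n <- length(y)
  for (it in seq_len(max_iter)) {
    r <- g(y)
    if (max(abs(r)) <= tol) break
    J <- matrix(0, n, n)
    eps <- pmax(abs(y), 1) * 1e-7
    for (j in seq_len(n)) {
      yp <- y; yp[j] <- yp[j] + eps[j]
      J[, j] <- (g(yp) - r) / eps[j]
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      y2 <- pmax(y + lam * step, 0)
      if (max(abs(g(y2))) < max(abs(r)) || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- y2
  }
  r <- g(y)
  if (max(abs(r)) > tol) {
    stop("equilibrium search did not converge (residual ",
         format(max(abs(r)), digits = 3), " > tol)", call. = FALSE)
  }
  names(y) <- system$species
  attr(y, "residual") <- max(abs(r))
  y
}

#' Relative sensitivity of a model output to a kinetic parameter
#'
#' Central finite difference in relative (log) units: the elasticity
#' `d ln(output) / d ln(parameter)` estimated by perturbing the parameter
#' by `±delta` (multiplicatively). For an unregulated species, the
#' equilibrium `beta/gamma` has sensitivity exactly +1 to `beta` and -1 to
#' `gamma`. Falls back to the difference normalized by the unperturbed
#' output when the output is near zero.
#'
#' @param system an `ode_system`.
#' @param output a species name.
#' @param parameter a string `"beta:SPECIES"`, `"gamma:SPECIES"`,
#'   `"x0:SPECIES"`, `"theta:SRC->TGT"` or `"h:SRC->TGT"`.
#' @param delta relative perturbation in (0, 0.5].
#' @param target `"equilibrium"` (default) or `"end_time"`.
#' @param t_end,x_start used for the chosen target.
#' @return the sensitivity coefficient (a number).
#' @export
ode_sensitivity <- function(system, output, parameter, delta = 0.05,
                            target = c("equilibrium", "end_time"),
                            t_end = 50, x_start = NULL) {
  stopifnot(inherits(system, "ode_system"), delta > 0, delta <= 0.5)
  target <- match.arg(target)
  if (!output %in% system$species) stop("unknown output species", call. = FALSE)

  perturb <- function(fac) {
    kin <- system$kinetics
    parts <- strsplit(parameter, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("parameter must look like \"beta:ERK\" or \"theta:ERK->HIF-1\"",
           call. = FALSE)
    }
    field <- parts[1]; key <- parts[2]
    if (field %in% c("beta", "gamma", "x0")) {
      i <- match(key, kin$species$name)
      if (is.na(i)) stop("unknown species in parameter", call. = FALSE)
      kin$species[[field]][i] <- kin$species[[field]][i] * fac
    } else if (field %in% c("theta", "h")) {
      ek <- paste0(kin$edges$source, "->", kin$edges$target)
      i <- match(key, ek)
      if (is.na(i)) stop("unknown edge in parameter", call. = FALSE)
      kin$edges[[field]][i] <- kin$edges[[field]][i] * fac
    } else stop("unknown parameter field ", dQuote(field), call. = FALSE)
    base <- if (system$regulation == "table") system$model else system$network
    brn_to_ode(base, kin, regulation = system$regulation)
  }

  value <- function(sys) {
    y <- switch(target,
                equilibrium = ode_equilibrium(sys, x_start = x_start,
                                              tol = 1e-8),
                end_time = {
                  tr <- attr(simulate_ode(sys, t_end, n_points = 101,
                                          x0 = x_start), "matrix")
                  stats::setNames(tr[nrow(tr), -1], sys$species)
                })
    unname(y[output])
  }

  yp <- value(perturb(1 + delta))
  ym <- value(perturb(1 - delta))
  y0 <- value(system)
  if (min(yp, ym) > 0 && y0 > 1e-12) {
    (log(yp) - log(ym)) / (log(1 + delta) - log(1 - delta))
  } else {
    denom <- if (abs(y0) > 1e-12) y0 else 1
    ((yp - ym) / denom) / (2 * delta)
  }
}
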