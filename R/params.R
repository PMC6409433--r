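# Free-parameter template: maps the optimizer's unconstrained vector to the
# full parameter state and chains gradients back, honouring equality ties and
# constant pins.
#
# Slot ids: "tau[h]", "theta[k]", "f[k]", "g[k,h]" ("g[h]" under shared g),
# "eps[k]", "c", "t".  Positive parameters are optimized on the log scale;
# epsilon on a scaled logit over (0, 0.5).

#' Equality constraints and parameter pins
#'
#' @param ties A list of character vectors; the slots named in each vector
#'   are constrained to be equal (estimated as one free parameter).  Ties
#'   must join slots of the same kind (e.g. two mutation rates).
#' @param pins A named numeric vector fixing slots to constants, e.g.
#'   `c("f[2]" = 4/3)`.
#' @return An object of class `"constraint_set"`.
#' @export
#' @examples
#' constraint_set(ties = list(c("theta[1]", "theta[2]")))
#' constraint_set(pins = c("f[2]" = 4/3), ties = list(c("g[1,1]", "g[2,1]")))
constraint_set <- function(ties = list(), pins = numeric(0)) {
  if (!is.list(ties) || !all(vapply(ties, is.character, logical(1))))
    stop("ties must be a list of character vectors of slot ids")
  if (length(pins) && (is.null(names(pins)) || any(names(pins) == "")))
    stop("pins must be a named numeric vector")
  structure(list(ties = ties, pins = pins), class = "constraint_set")
}

.slot_kind <- function(id) sub("\\[.*$", "", id)

## Build the template.  `model` supplies the structure (K, H, shared_g,
## divergence on/off) and the values of fixed slots.
.make_template <- function(model, data, use_profile = TRUE,
                           use_divergence = NULL, constraints = NULL,
                           fit_epsilon = FALSE) {
  K <- length(model$loci)
  H <- model$epochs$H
  if (is.null(use_divergence))
    use_divergence <- !is.null(model$divergence) && !is.null(data$x)
  if (use_divergence && is.null(model$divergence))
    model$divergence <- list(c = 1, t = 1)
  if (use_divergence && is.null(data$x))
    stop("use_divergence = TRUE but the dataset has no substitution counts")
  if (is.null(constraints)) constraints <- constraint_set()
  if (!inherits(constraints, "constraint_set"))
    stop("constraints must be a constraint_set")
  fit_eps_vec <- rep(isTRUE(fit_epsilon), K)
  if (data$folded && any(fit_eps_vec))
    stop("polarization error cannot be estimated from folded spectra")

  ## candidate free slots in canonical order
  ids <- character(0)
  if (H > 1L) ids <- c(ids, sprintf("tau[%d]", seq_len(H - 1L)))
  if (!use_profile) ids <- c(ids, sprintf("theta[%d]", seq_len(K)))
  if (H > 1L && K > 1L)
    ids <- c(ids, sprintf("f[%d]", setdiff(seq_len(K), model$ref)))
  if (H > 1L) {
    ids <- c(ids, if (model$shared_g) sprintf("g[%d]", seq_len(H - 1L))
             else as.vector(t(outer(seq_len(K), seq_len(H - 1L),
                                    function(k, h) sprintf("g[%d,%d]", k, h)))))
  }
  if (any(fit_eps_vec)) ids <- c(ids, sprintf("eps[%d]", which(fit_eps_vec)))
  if (use_divergence) ids <- c(ids, "c", "t")

  pins <- constraints$pins
  if (use_profile && any(.slot_kind(names(pins)) == "theta"))
    stop("theta cannot be pinned under the profile likelihood; ",
         "set use_profile = FALSE")
  badpin <- setdiff(names(pins), ids)
  if (length(badpin))
    stop("pinned slots not free in this model: ", paste(badpin, collapse = ", "))
  ids <- setdiff(ids, names(pins))

  ## ties: union-find over remaining free slots.  Under the profile route,
  ## theta ties define concentration groups instead of optimizer parameters.
  canon <- stats::setNames(ids, ids)
  find <- function(x) { while (canon[[x]] != x) x <- canon[[x]]; x }
  for (tie in constraints$ties) {
    if (length(unique(.slot_kind(tie))) != 1L)
      stop("ties must join slots of the same kind: ",
           paste(tie, collapse = ", "))
    if (use_profile && .slot_kind(tie[1L]) == "theta") next
    bad <- setdiff(tie, ids)
    if (length(bad))
      stop("tied slots not free in this model: ", paste(bad, collapse = ", "))
    root <- find(tie[1L])
    for (s in tie[-1L]) canon[[find(s)]] <- root
  }
  canon <- vapply(names(canon), find, character(1))
  free_ids <- unique(unname(canon))
  index <- stats::setNames(match(canon, free_ids), names(canon))

  ## theta groups for profile concentration (loci sharing one theta)
  theta_groups <- NULL
  if (use_profile) {
    grp_key <- rep(NA_character_, K)
    for (tie in constraints$ties) {
      if (.slot_kind(tie[1L]) == "theta") {
        ks <- as.integer(sub("theta\\[(\\d+)\\]", "\\1", tie))
        grp_key[ks] <- tie[1L]
      }
    }
    grp_key[is.na(grp_key)] <- sprintf("solo%d", which(is.na(grp_key)))
    theta_groups <- unname(split(seq_len(K), factor(grp_key, unique(grp_key))))
  }

  base_state <- .state_from_model(model)
  ## apply pins to the base state (they stay fixed there)
  for (nm in names(pins)) base_state <- .assign_slot(base_state, nm, pins[[nm]],
                                                     model$shared_g)
  structure(list(
    K = K, H = H, ref = model$ref, shared_g = model$shared_g,
    use_profile = use_profile, use_divergence = use_divergence,
    fit_eps = fit_eps_vec, free_ids = free_ids, index = index,
    theta_groups = theta_groups, base_state = base_state,
    n_free = length(free_ids),
    n_free_total = length(free_ids) +
      if (use_profile) length(theta_groups) else 0L,
    model = model), class = "sfs_template")
}

.assign_slot <- function(state, id, value, shared_g) {
  value <- unname(value)
  kind <- .slot_kind(id)
  idx <- as.integer(strsplit(gsub("[^0-9,]", "", id), ",")[[1L]])
  switch(kind,
    tau   = { state$tau[idx[1L]] <- value; state },
    theta = { state$theta[idx[1L]] <- value; state },
    f     = { state$f[idx[1L]] <- value; state },
    g     = {
      if (shared_g) state$g[, idx[1L]] <- value
      else state$g[idx[1L], idx[2L]] <- value
      state
    },
    eps   = { state$eps[idx[1L]] <- value; state },
    c     = { state$c <- value; state },
    t     = { state$t <- value; state },
    stop("unknown slot id: ", id))
}

.slot_value <- function(state, id, shared_g) {
  kind <- .slot_kind(id)
  idx <- as.integer(strsplit(gsub("[^0-9,]", "", id), ",")[[1L]])
  switch(kind,
    tau = state$tau[idx[1L]], theta = state$theta[idx[1L]],
    f = state$f[idx[1L]],
    g = if (shared_g) state$g[1L, idx[1L]] else state$g[idx[1L], idx[2L]],
    eps = state$eps[idx[1L]], c = state$c, t = state$t)
}

.grad_slot <- function(grad, id, shared_g) {
  kind <- .slot_kind(id)
  idx <- as.integer(strsplit(gsub("[^0-9,]", "", id), ",")[[1L]])
  switch(kind,
    tau = grad$tau[idx[1L]], theta = grad$theta[idx[1L]],
    f = grad$f[idx[1L]],
    g = if (shared_g) sum(grad$g[, idx[1L]]) else grad$g[idx[1L], idx[2L]],
    eps = grad$eps[idx[1L]], c = grad$c, t = grad$t)
}

## natural value <-> unconstrained coordinate
.to_z <- function(value, kind) {
  if (kind == "eps") stats::qlogis(pmin(pmax(value / 0.5, 1e-12), 1 - 1e-12))
  else log(value)
}
.from_z <- function(z, kind) {
  if (kind == "eps") 0.5 * stats::plogis(z) else exp(z)
}
.dnat_dz <- function(value, kind) {
  if (kind == "eps") value * (1 - 2 * value) else value
}

## state -> z at the template's free slots
.template_pack <- function(template, state) {
  vapply(template$free_ids, function(id)
    .to_z(.slot_value(state, id, template$shared_g), .slot_kind(id)),
    numeric(1))
}

## z -> state (base state with free/tied slots overwritten)
.template_unpack <- function(template, z) {
  state <- template$base_state
  for (nm in names(template$index)) {
    kind <- .slot_kind(nm)
    state <- .assign_slot(state, nm,
                          .from_z(z[template$index[[nm]]], kind),
                          template$shared_g)
  }
  state
}

## natural-coordinate gradient list -> gradient wrt z
.template_pack_grad <- function(template, state, grad) {
  gz <- numeric(template$n_free)
  for (nm in names(template$index)) {
    kind <- .slot_kind(nm)
    v <- .slot_value(state, nm, template$shared_g)
    j <- template$index[[nm]]
    gz[j] <- gz[j] + .grad_slot(grad, nm, template$shared_g) * .dnat_dz(v, kind)
  }
  gz
}

## objective closures (negative loglik) with a one-slot memo
.make_objective <- function(template, data, B) {
  opts <- list(use_divergence = template$use_divergence,
               profile = template$use_profile,
               theta_groups = template$theta_groups)
  cache <- new.env(parent = emptyenv())
  cache$z <- NULL
  evalz <- function(z) {
    if (!is.null(cache$z) && length(z) == length(cache$z) &&
        all(z == cache$z)) return(cache$res)
    state <- .template_unpack(template, z)
    res <- .ll_eval(state, data, B, opts, want_grad = TRUE)
    res$state <- state
    cache$z <- z
    cache$res <- res
    res
  }
  big <- 1e10
  list(
    fn = function(z) {
      if (any(!is.finite(z))) return(big)
      res <- evalz(z)
      if (!isTRUE(res$feasible) || !is.finite(res$loglik)) big else -res$loglik
    },
    gr = function(z) {
      if (any(!is.finite(z))) return(numeric(template$n_free))
      res <- evalz(z)
      if (!isTRUE(res$feasible) || !is.finite(res$loglik))
        return(numeric(template$n_free))
      st <- res$state
      st$theta <- res$theta   # concentrated values, for the chain rule
      -.template_pack_grad(template, st, res$grad)
    },
    evalz = evalz)
}

## uniform log-space start boxes, by slot kind
.start_box <- function(kind) {
  switch(kind,
    theta = c(1e-5, 1e-1), f = c(0.05, 20), g = c(0.05, 50),
    tau = c(1e-3, 10), c = c(0.1, 10), t = c(0.1, 50),
    eps = c(0.005, 0.4),
    stop("no start box for kind ", kind))
}

.random_start <- function(template) {
  vapply(template$free_ids, function(id) {
    kind <- .slot_kind(id)
    box <- .start_box(kind)
    v <- exp(stats::runif(1L, log(box[1L]), log(box[2L])))
    .to_z(v, kind)
  }, numeric(1))
}
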