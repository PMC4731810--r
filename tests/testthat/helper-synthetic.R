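# shared builders for the test suite

# a dichromat whose receptors ARE two camera channels (visG, uvB): its fitted
# mapping is exact (R^2 = 1) and its cone catches equal those channel values,
# so expected metric values can be computed by hand
identity_dichromat <- function(cone_ratio = c(1, 1)) {
  cam <- camera_gaussian()
  visual_system("camdi", c("g", "u"), cone_ratio,
                list(receptors = "g", weights = 1),
                list(g = cam$visG, u = cam$uvB))
}

fit_identity_dichromat <- function(system = identity_dichromat()) {
  lib <- generate_spectra(60, seed = 99)
  fit_predator_model(system, lib, camera_gaussian())
}

# wrap a bare array as a cone-catch image for metric functions
as_cone_image <- function(arr, receptors, system = "test", px_per_mm = 1) {
  dimnames(arr)[[3]] <- receptors
  structure(arr, system = system, px_per_mm = px_per_mm, floor = 1e-6,
            class = c("cone_image", "array"))
}

# independent Cox oracle: explicit enumeration of the partial likelihood
# (no ties), maximized numerically -- kept free of any package code paths
brute_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

brute_cox_beta <- function(time, event, x) {
  optimize(function(b) -brute_cox_loglik(b, time, event, x),
           interval = c(-20, 20), tol = 1e-12)$minimum
}

# hand product-limit estimator for censoring-free data
empirical_survival <- function(times, at) {
  vapply(at, function(t) mean(times > t), numeric(1))
}
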