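# shared fixtures: small parameter grids and quick synthetic cohorts

simple_param_grid <- function() {
  list(
    ddm_params(v = 0.8, a = 1.0, z_rel = 0.5, ter = 0.25),
    ddm_params(v = 1.2, a = 1.5, z_rel = 0.5, ter = 0.30),
    ddm_params(v = 1.8, a = 0.8, z_rel = 0.4, ter = 0.35),
    ddm_params(v = 2.5, a = 1.2, z_rel = 0.6, ter = 0.20),
    ddm_params(v = 0.5, a = 2.0, z_rel = 0.5, ter = 0.40),
    ddm_params(v = 1.5, a = 1.0, z_rel = 0.55, ter = 0.30)
  )
}

full_param_grid <- function() {
  list(
    ddm_params(v = 1.2, a = 1.2, z_rel = 0.5, ter = 0.30,
               sv = 0.8, sz_rel = 0.2, ster = 0.15),
    ddm_params(v = 0.9, a = 1.6, z_rel = 0.45, ter = 0.35,
               sv = 0.5, sz_rel = 0.1, ster = 0.10),
    ddm_params(v = 2.0, a = 0.9, z_rel = 0.5, ter = 0.25,
               sv = 1.2, sz_rel = 0.3, ster = 0.08)
  )
}

# tiny two-group trial table with exact control over accuracy / rt
toy_trials <- function() {
  data.frame(
    participant = rep(c("p1", "p2"), each = 4),
    group = rep(c("A", "B"), each = 4),
    block = rep(1:2, 4),
    rt = c(0.5, 0.6, 0.7, 0.8, 0.4, 0.5, 0.9, 1.0),
    correct = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    choice = rep(c("left", "right"), 4),
    stringsAsFactors = FALSE
  )
}
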