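# shared fixtures: canonical curves and small designs built in code

std_percent_hill <- function(idm = 1, n = 1) hill_params(idm, n, 0, 100)

self_pair <- function(n = 1, idm = 1) {
  h <- std_percent_hill(idm, n)
  additive_pair(h, h)
}

# small checkerboard design for fast tests
small_design <- function(replicates = 1) {
  checkerboard_design(
    concsA = dilution_series(8, 6, 2, "max"),
    singleA = dilution_series(1, 9, 2, "centered"),
    singleB = dilution_series(1, 9, 2, "centered"),
    replicates = replicates)
}

# noise-free combination data from a braid surface on a dense grid
braid_fixture <- function(bp, design = standard_bias_design(),
                          noise = noise_spec()) {
  surf <- function(a, b) braid_effect(bp, a, b)
  chk <- simulate_checkerboard(surf, design, noise)
  hA <- hill_params(bp$idmA, bp$na, bp$e0, bp$efA)
  hB <- hill_params(bp$idmB, bp$nb, bp$e0, bp$efB)
  sa <- simulate_single_agents(hA, hB, design, noise)
  combine_combination_data(chk, sa$A, sa$B)
}
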