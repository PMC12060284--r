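# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# uniform winter Norwegian-shelf profile (7 degC, 34 ppt)
ncs_profile <- function(H) data.frame(depth = c(0, H), T = 7, S = 34)

# single-bubble run and deposition for the 65 m reference case
bubble65 <- function() fixture("bubble65", function()
  integrate_bubble(65, d0 = 4.5e-3, profile = ncs_profile(65)))

# shallow seasonal scenario
scen65 <- function() fixture("scen65", function() make_scenario(65, seed = 7))

# permanently well-mixed constant-wind scenario (box-model oracle conditions)
scen_mixed <- function() fixture("scen_mixed", function()
  make_scenario(30, scenario_config(k_mixed = 0.5, k_ceiling = 0.5,
                                    summer_onset = 1000, summer_end = 1001,
                                    wind_sd = 0), seed = 1))

# uniform deposition on a 30 m column, no direct bubble transport
dep_uniform30 <- function() deposition_profile(0:29, 1:30, rep(1 / 30, 30), 0)
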