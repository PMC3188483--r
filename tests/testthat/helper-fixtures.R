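# shared small fixtures: a coarse uncoupled sheet and a coarse wired sheet,
# built once per test run (wiring draw is the expensive part)

uncoupled_profiles <- function() {
  list(pp = connectivity_profile(0, 145),
       pfs = connectivity_profile(0, 92),
       fsp = connectivity_profile(0, 92))
}

# 32x32 P / 8x8 FS sheet with standard wiring
small_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network(scale = 0.2, seed = 99)
    net
  }
})

# tiny uncoupled sheet (4x4 P, 2x2 FS): pure feedforward responses
tiny_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) {
      net <<- build_network(scale = 4 / 160, profiles = uncoupled_profiles(),
                            seed = 5)
    }
    net
  }
})
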