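# Shared fixtures built in code.

default_noise <- receptor_noise()

# equal-noise viewer used by the closed-form JND examples
equal_noise <- receptor_noise(abundances = c(uv = 1, sw = 1, mw = 1, lw = 1),
                              weber = 0.05)

# a positive random cone catch (all five channels)
random_catch <- function() {
  q <- exp(rnorm(5, -1, 0.6))
  cone_catch(q[1], q[2], q[3], q[4], q[5])
}

# a catch displaced from `base` by log-catch deltas df (single cones) and
# dfl (double cone)
displaced_catch <- function(base, df, dfl = 0) {
  q <- unclass(base)
  cone_catch(q[["uv"]] * exp(df[1]), q[["sw"]] * exp(df[2]),
             q[["mw"]] * exp(df[3]), q[["lw"]] * exp(df[4]),
             q[["dbl"]] * exp(dfl))
}

# tiny world for pipeline smoke tests
small_world_config <- function(...) {
  world_config(n_per_species = 4, n_leaves = 3, ...)
}
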