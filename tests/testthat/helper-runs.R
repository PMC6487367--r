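# shared simulation fixtures, computed once per test run on first use
sw_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = sw_cache)) {
    assign(name, force(expr), envir = sw_cache)
  }
  get(name, envir = sw_cache)
}

default_model <- function() cached("model", assemble())

# steady B-type tetrapod walking (slow muscles on): bilateral-sync start,
# transition to tripod at 3 s, to tetrapod at 7.5 s, recorded to 12.5 s
tetrapod_run <- function() cached("tetrapod_run", {
  sched <- list(mode_command("set_gait", 3000, gait = "tripod"),
                mode_command("set_gait", 7500, gait = "tetrapod"))
  run_model(default_model(), sched, config = sim_config(t_end = 12500))
})

uncoupled_model <- function() cached("uncoupled_model", {
  assemble(contralateral = contralateral_config(FALSE, FALSE, FALSE, FALSE),
           ipsilateral = FALSE)
})
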