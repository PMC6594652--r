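# shared expensive fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

std_regions <- function() {
  if (is.null(.fixture_cache$regs))
    .fixture_cache$regs <- example_region_set(42)
  .fixture_cache$regs
}

# the criterion-1 world: 200 junctions, geometric clone sizes, error-free
std_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_reads(
      sim_config(seed = 101, n_junctions = 200), std_regions())
  .fixture_cache$sim
}

std_calls <- function() {
  if (is.null(.fixture_cache$calls))
    .fixture_cache$calls <- call_junctions(std_sim()$reads, std_regions())
  .fixture_cache$calls
}
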