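# Typed errors so the command-line wrapper can map failure stages to
# distinct exit codes.

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("seedpath_io_error", "seedpath_error")))
}

stop_network <- function(...) {
  stop(errorCondition(paste0(...), class = c("seedpath_network_error", "seedpath_error")))
}

stop_seeds <- function(...) {
  stop(errorCondition(paste0(...), class = c("seedpath_seed_error", "seedpath_error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("seedpath_input_error", "seedpath_error")))
}
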