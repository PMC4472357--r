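# Classed errors so callers (and the command-line wrapper) can distinguish
# configuration problems, malformed data, and undefined statistical
# procedures.

.cfg_err <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("bdmseed_config_error", "error", "condition"),
                      call = call))
}

.data_err <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("bdmseed_data_error", "error", "condition"),
                      call = call))
}

.stat_err <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("bdmseed_stat_error", "error", "condition"),
                      call = call))
}
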