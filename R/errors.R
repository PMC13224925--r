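# Condition helpers: every user-facing failure is signalled with a condition
# class so the command-line wrapper can map it onto an exit code
# (hf_config_error -> 1, hf_io_error -> 2).

hf_stop <- function(msg, class) {
  rlang::abort(msg, class = c(class, "hf_error"))
}

hf_config_error <- function(msg) hf_stop(msg, "hf_config_error")
hf_io_error     <- function(msg) hf_stop(msg, "hf_io_error")
hf_parse_error  <- function(msg) hf_stop(msg, "hf_parse_error")
hf_data_error   <- function(msg) hf_stop(msg, "hf_data_error")
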