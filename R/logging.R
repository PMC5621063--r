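# One-line structured stage logging, off by default. Enable with
# options(patchscale.verbose = TRUE).
log_stage <- function(stage, detail) {
  if (isTRUE(getOption("patchscale.verbose", FALSE)))
    message(sprintf("[patchscale] %s %s | %s",
                    format(Sys.time(), "%H:%M:%OS2"), stage, detail))
  invisible(NULL)
}
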