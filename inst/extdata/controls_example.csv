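action,at_time,after_sweep,loop_index,runonce_index,sweep_name,line,channel,protocol
uncheck_loop,,3,1,,,,,
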