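id	start	end
RRM1	59	143
RRM2	184	206
RRM3	337	411
RRM4	454	529
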