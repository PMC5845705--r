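period	pattern	count
before_3w	asynchronous	7
before_3w	loosely_synchronous	2
after_3w	synchronous	6
after_3w	asynchronous	2
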