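#sentence=1 speaker=1 block=1
de	jongen	ziet	een	kikkert
de	jongen	ziet	de	[X]
de	jongen	zag	[B]	kokkin
de	jongen	zag	geen	kikkers
de	hond	zoekt	een	[X]
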