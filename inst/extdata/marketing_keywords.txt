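# keywords marking marketing posts (e.g. battery strength specs in ads)
1100mah
coupon
discount
promo code
free shipping
wholesale
order now
buy now
clearance
restocked
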