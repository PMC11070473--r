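{"color":{"fx":610.5,"fy":610.10000000000002,"cx":421.30000000000001,"cy":237.59999999999999,"width":848,"height":480},"depth":{"fx":426.19999999999999,"fy":426.19999999999999,"cx":423.39999999999998,"cy":239.09999999999999,"width":848,"height":480},"depth_to_color":{"R":[0.99999390765779039,0,0.0034906514152237321,0,1,0,-0.0034906514152237321,0,0.99999390765779039],"t":[0.0147,0.00020000000000000001,-0.00029999999999999997]},"depth_scale":0.001}
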