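iVBORw0KGgoAAAANSUhEUgAAABEAAAAMCAIAAAALR8HoAAACe0lEQVR42gFwAo/9AIgm2RbN+yHGwf+Rp2FWWnAkFtpuwhLN242IABYOtoay64GTM7UBHBiMU8eG7WLC+XFEWgI0CTTE9UV25vak8ZRovXfyXwA0Xl5c8B5JoX42ZXOKZZUKC7mprnajohOxugCkDBtX7f4CGHWpxkInttXpL6ED2Hj5NQBbLIUxBWFYVhGk7CPusy15AhHT7jRRmCiq9rrL1SKOF6LUALnZRhDCtKH1c0wqwwkSwh95VbO+NsJaiTRjEW2qf/g8kxhy95Wj5LAZjK0PJETHEMWIwgGk19ONQB/3RiXfHmAyyfhG+Uq3zufE4OsomfQFp2Mmk/H+HtuJ7HwYxpG8MFCjHlJ421EB9yJ9NkfsHQDq2Mh+xVCh792tZC30C0QhMwF6Ofs8gLZGxcRTgOMGzPmwx5x2Qw8YLWn4BJAyrI6tEez6SekBHZEqCG420fB5+TV286ooGO0B4YYRCKukD87UrZYw38VfSLLzdBiPCQD6DtUKXGpvdAkFzkoeedd1yDFjFhLp5eDez0mxqFM9fQa4rrHSAqOa0cYjRTwu1RcvLTMBR94Nh4VxFJ6z/vyaYeOoiNuB/Ax55Ww9LWwOoUD/DdWm7D3pJuqXMDoEd3k2Q+1eyO76AYHkBRit1mz5LmoywLTSEbSw7gATVQ8ybYpa6qzO44rdUCg68qo67G7eumrZUaOUtiHLsQHWw8cwVsxUzelIgdIaKd+lJ2AapaKc9wQRPHc88CEOLQTbwswGLNxaSZB/0u4sQ8B0d5kAvpT7ZwXvNhbfy0ZMVZVogVUf/rGfeNpdo+EISXXjO7pBWdKw7ewOuz4N21XGCEgFQOvqT8wxJqrZIjwAAAAASUVORK5CYII=
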